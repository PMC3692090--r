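#' Energy minimization
#'
#' Steepest-descent geometry optimization with the workflow's protocol
#' constants: at most 1500 steps, convergence when the maximum per-atom
#' force norm drops to 1.0 kJ/mol/nm, nonbonded cutoff 1.4 nm, in vacuo.
#' Before minimization an eligibility pre-check reports every reason a
#' structure is unsuitable; a negative report deactivates minimization
#' downstream but never blocks modification output.
#'
#' @name minimize
NULL

.ELIG_LIGAND <- "non-standard residues or unique ligands"
.ELIG_MISSING <- "missing atoms or residues"
.ELIG_FORMAT <- "non-standard formatting of PDB file"

#' Minimization configuration
#'
#' @param max_steps iteration cap (default 1500).
#' @param fmax convergence threshold on the maximum per-atom force norm,
#'   kJ/mol/nm (default 1.0).
#' @param initial_step initial displacement of the largest-force atom, nm.
#' @param cutoff nonbonded cutoff, nm (default 1.4).
#' @param grow,shrink step-size scaling on accepted / rejected steps.
#' @return a `ptm_min_config` list.
#' @export
minimization_config <- function(max_steps = 1500L, fmax = 1.0,
                                initial_step = 0.01, cutoff = 1.4,
                                grow = 1.2, shrink = 0.5) {
  stopifnot(max_steps >= 1L, fmax > 0, initial_step > 0, cutoff > 0,
            grow > 1, shrink > 0, shrink < 1)
  structure(list(max_steps = as.integer(max_steps), fmax = fmax,
                 initial_step = initial_step, cutoff = cutoff,
                 grow = grow, shrink = shrink),
            class = "ptm_min_config")
}

#' Check whether a structure is suitable for minimization
#'
#' Lists every failure reason found, not just the first.
#'
#' @param st a `ptm_structure`.
#' @param registry a `ptm_registry`.
#' @return list with `eligible` (flag) and `reasons` (character; empty iff
#'   eligible).
#' @export
check_minimizable <- function(st, registry = default_registry()) {
  reasons <- character()
  if (nrow(st$het) > 0L) reasons <- c(reasons, .ELIG_LIGAND)
  idx <- .residue_index(st$atoms)
  if (length(idx) == 0L) {
    reasons <- c(reasons, .ELIG_MISSING)
    return(list(eligible = FALSE, reasons = unique(reasons)))
  }
  nres <- max(idx)
  chain_of <- tapply(st$atoms$chain_id, idx, function(x) x[1L])
  for (ri in seq_len(nres)) {
    rows <- which(idx == ri)
    rn <- st$atoms$res_name[rows[1L]]
    blk <- registry$blocks[[rn]]
    if (is.null(blk)) {
      reasons <- c(reasons, .ELIG_LIGAND)
      next
    }
    names_here <- st$atoms$name[rows]
    if (length(setdiff(blk$atoms$name, names_here)))
      reasons <- c(reasons, .ELIG_MISSING)
    last_of_chain <- ri == nres || chain_of[[ri + 1L]] != chain_of[[ri]]
    allowed <- c(blk$atoms$name, if (last_of_chain) "OXT")
    if (length(setdiff(names_here, allowed)) || anyDuplicated(names_here))
      reasons <- c(reasons, .ELIG_FORMAT)
  }
  reasons <- unique(reasons)
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

.max_force <- function(f) if (nrow(f) == 0L) 0 else max(sqrt(rowSums(f * f)))

#' Steepest-descent minimization
#'
#' Adaptive-step steepest descent: the trial step moves every atom along the
#' force, scaled so the largest per-atom displacement is the current step
#' size; downhill steps are accepted and grow the step (x1.2), uphill trials
#' are rejected and shrink it (x0.5).  Terminates when the maximum per-atom
#' force norm reaches `fmax` (converged), after `max_steps` iterations
#' (not converged), or when the step size underflows below 1e-10 nm
#' (stalled; flagged distinctly).  Deterministic for fixed inputs.
#'
#' @param positions N x 3 starting coordinates, nm.
#' @param topology a `ptm_topology`.
#' @param config a `ptm_min_config`; defaults to the protocol constants.
#' @return a `ptm_min_result`: `positions` (final), `converged`, `stalled`,
#'   `steps_used`, `energy_trace` (energy after each accepted step,
#'   non-increasing), `final_fmax`, `final_energy`.
#' @export
steepest_descent <- function(positions, topology,
                             config = minimization_config()) {
  x <- as.matrix(positions)
  ef <- energy_forces(x, topology, cutoff = config$cutoff)
  if (!is.finite(ef$total)) stop("non-finite energy at start of minimization")
  e <- ef$total
  fmat <- ef$forces
  s <- config$initial_step
  trace <- e
  steps <- 0L
  converged <- FALSE
  stalled <- FALSE
  while (steps < config$max_steps) {
    fnow <- .max_force(fmat)
    if (fnow <= config$fmax) { converged <- TRUE; break }
    trial <- x + (s / fnow) * fmat
    steps <- steps + 1L
    ef_t <- tryCatch(energy_forces(trial, topology, cutoff = config$cutoff),
                     error = function(cond) NULL)
    if (!is.null(ef_t) && is.finite(ef_t$total) && ef_t$total < e) {
      x <- trial
      e <- ef_t$total
      fmat <- ef_t$forces
      trace <- c(trace, e)
      s <- s * config$grow
    } else {
      s <- s * config$shrink
      if (s < 1e-10) { stalled <- TRUE; break }
    }
  }
  if (!converged && !stalled && .max_force(fmat) <= config$fmax) converged <- TRUE
  structure(list(positions = x, converged = converged, stalled = stalled,
                 steps_used = steps, energy_trace = trace,
                 final_fmax = .max_force(fmat), final_energy = e),
            class = "ptm_min_result")
}

#' @export
print.ptm_min_result <- function(x, ...) {
  cat(sprintf("steepest descent: %s after %d step(s); E = %.4f kJ/mol, fmax = %.4g kJ/mol/nm\n",
              if (x$converged) "converged" else if (x$stalled) "stalled" else "step limit reached",
              x$steps_used, x$final_energy, x$final_fmax))
  invisible(x)
}

#' Echo of the effective minimization settings (.mdp-style)
#'
#' @param config a `ptm_min_config`.
#' @param flavour force-field flavour tag.
#' @return character vector of settings lines, suitable for a provenance
#'   file alongside the minimization log.
#' @export
settings_echo <- function(config = minimization_config(), flavour = "54a7") {
  c("; effective minimization settings (provenance echo)",
    "integrator               = steep",
    sprintf("nsteps                   = %d", config$max_steps),
    sprintf("emtol                    = %g", config$fmax),
    sprintf("emstep                   = %g", config$initial_step),
    sprintf("rvdw                     = %g", config$cutoff),
    sprintf("rcoulomb                 = %g", config$cutoff),
    "pbc                      = no",
    sprintf("; force-field flavour    = %s", flavour))
}
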