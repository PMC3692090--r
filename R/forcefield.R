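#' United-atom molecular-mechanics layer
#'
#' Builds a topology (bonds, angles, dihedrals, nonbonded pair list with 1-2
#' and 1-3 exclusions) for a (modified) protein from the packaged building
#' blocks, and evaluates energy and forces:
#' harmonic bonds and angles, cosine proper dihedrals, Lennard-Jones 12-6 and
#' Coulomb with a plain cutoff (default 1.4 nm), in vacuo.  Forces are the
#' exact negative gradient of the energy; parameter fidelity to any
#' production force field is a declared non-goal, gradient correctness is
#' the tested contract.
#'
#' @name forcefield
NULL

.COULOMB_K <- 138.935458  # kJ mol^-1 nm e^-2

.type_class <- function(type) {
  ifelse(type == "H", "H", substr(type, 1, 1))
}

.lookup_bond <- function(params, ti, tj) {
  bt <- params$bondtypes
  ex <- bt[!bt$class, , drop = FALSE]
  hit <- which((ex$ti == ti & ex$tj == tj) | (ex$ti == tj & ex$tj == ti))
  if (length(hit)) return(ex[hit[1L], c("b0", "kb")])
  ci <- .type_class(ti); cj <- .type_class(tj)
  cl <- bt[bt$class, , drop = FALSE]
  hit <- which((cl$ti == ci & cl$tj == cj) | (cl$ti == cj & cl$tj == ci))
  if (length(hit)) return(cl[hit[1L], c("b0", "kb")])
  stop(sprintf("no bond parameters for type pair %s-%s", ti, tj))
}

.lookup_angle <- function(params, ti, tj, tk) {
  an <- params$angletypes
  exact <- an[an$ti != "X", , drop = FALSE]
  hit <- which((exact$ti == ti & exact$tj == tj & exact$tk == tk) |
               (exact$ti == tk & exact$tj == tj & exact$tk == ti))
  if (length(hit)) return(exact[hit[1L], c("theta0", "kt")])
  wild <- an[an$ti == "X", , drop = FALSE]
  hit <- which(wild$tj == tj)
  if (length(hit)) return(wild[hit[1L], c("theta0", "kt")])
  stop(sprintf("no angle parameters centered on type %s", tj))
}

.lookup_dihedral <- function(params, tj, tk) {
  dt <- params$dihedraltypes
  exact <- dt[dt$ti != "X", , drop = FALSE]
  hit <- which((exact$ti == tj & exact$tj == tk) | (exact$ti == tk & exact$tj == tj))
  if (length(hit)) return(exact[hit[1L], c("phis", "n", "kp")])
  dt[dt$ti == "X", c("phis", "n", "kp")][1L, ]
}

#' Build a molecular-mechanics topology for a structure
#'
#' Every residue (canonical or modification product) must have a packaged
#' building block; HETATM content has no parameters and raises the
#' unknown-residue error that mirrors the minimization-eligibility failure.
#' A terminal OXT is accepted on the last residue of a chain.
#'
#' @param st a `ptm_structure`.
#' @param registry a `ptm_registry`.
#' @param flavour force-field flavour tag, `"54a7"` or `"45a3"`; recorded in
#'   outputs (both select the single packaged parameter table).
#' @return a `ptm_topology`: atoms, bonds, angles, dihedrals, nonbonded
#'   pair list, exclusions, flavour.
#' @export
build_topology <- function(st, registry = default_registry(),
                           flavour = c("54a7", "45a3")) {
  flavour <- match.arg(flavour)
  params <- registry$params
  if (nrow(st$het) > 0L)
    stop(sprintf("unknown residue: HETATM content (%s) has no building block (unique ligand)",
                 paste(unique(st$het$res_name), collapse = ", ")))
  atoms_df <- st$atoms
  if (nrow(atoms_df) == 0L) stop("empty structure")
  idx <- .residue_index(atoms_df)
  nres <- max(idx)
  chain_of <- tapply(atoms_df$chain_id, idx, function(x) x[1L])

  n <- nrow(atoms_df)
  type <- character(n); charge <- numeric(n); mass <- numeric(n)
  bond_i <- integer(); bond_j <- integer()
  prev_C <- NA_integer_; prev_chain <- ""
  for (ri in seq_len(nres)) {
    rows <- which(idx == ri)
    rn <- atoms_df$res_name[rows[1L]]
    blk <- registry$blocks[[rn]]
    if (is.null(blk))
      stop(sprintf("unknown residue '%s': no building block packaged", rn))
    names_here <- atoms_df$name[rows]
    last_of_chain <- ri == nres || chain_of[[ri + 1L]] != chain_of[[ri]]
    allowed_extra <- if (last_of_chain) "OXT" else character()
    missing_atoms <- setdiff(blk$atoms$name, names_here)
    if (length(missing_atoms))
      stop(sprintf("incomplete residue %s %s%d: missing atom(s) %s",
                   rn, atoms_df$chain_id[rows[1L]], atoms_df$res_seq[rows[1L]],
                   paste(missing_atoms, collapse = ", ")))
    extra <- setdiff(names_here, c(blk$atoms$name, allowed_extra))
    if (length(extra))
      stop(sprintf("unexpected atom(s) %s in residue %s %s%d",
                   paste(extra, collapse = ", "), rn,
                   atoms_df$chain_id[rows[1L]], atoms_df$res_seq[rows[1L]]))
    m <- match(names_here, blk$atoms$name)
    type[rows] <- ifelse(is.na(m), "O", blk$atoms$type[m])       # OXT
    charge[rows] <- ifelse(is.na(m), 0, blk$atoms$charge[m])
    mass[rows] <- ifelse(is.na(m), params$atomtypes$mass[match("O", params$atomtypes$type)],
                         blk$atoms$mass[m])
    gi <- function(nm) rows[match(nm, names_here)]
    for (bi in seq_len(nrow(blk$bonds))) {
      bond_i <- c(bond_i, gi(blk$bonds$a[bi]))
      bond_j <- c(bond_j, gi(blk$bonds$b[bi]))
    }
    if ("OXT" %in% names_here) {
      bond_i <- c(bond_i, gi("C")); bond_j <- c(bond_j, gi("OXT"))
    }
    this_chain <- chain_of[[ri]]
    if (!is.na(prev_C) && identical(prev_chain, this_chain)) {
      bond_i <- c(bond_i, prev_C); bond_j <- c(bond_j, gi("N"))
    }
    prev_C <- gi("C"); prev_chain <- this_chain
  }

  # adjacency
  nb <- vector("list", n)
  for (b in seq_along(bond_i)) {
    nb[[bond_i[b]]] <- c(nb[[bond_i[b]]], bond_j[b])
    nb[[bond_j[b]]] <- c(nb[[bond_j[b]]], bond_i[b])
  }
  nb <- lapply(nb, function(x) sort(unique(x)))

  bonds <- data.frame(i = bond_i, j = bond_j)
  bp <- t(mapply(function(i, j) unlist(.lookup_bond(params, type[i], type[j])),
                 bonds$i, bonds$j))
  bonds$b0 <- bp[, 1]; bonds$kb <- bp[, 2]

  angles <- list()
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2L) {
      cmb <- utils::combn(nbs, 2L)
      for (ci in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, ci], j, cmb[2, ci])
    }
  }
  angles <- if (length(angles)) as.data.frame(do.call(rbind, angles)) else
    data.frame(V1 = integer(), V2 = integer(), V3 = integer())
  names(angles) <- c("i", "j", "k")
  if (nrow(angles)) {
    ap <- t(mapply(function(i, j, k)
      unlist(.lookup_angle(params, type[i], type[j], type[k])),
      angles$i, angles$j, angles$k))
    angles$theta0 <- ap[, 1]; angles$kt <- ap[, 2]
  } else { angles$theta0 <- numeric(); angles$kt <- numeric() }

  dihedrals <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds$i[b]; k <- bonds$j[b]
    ni <- setdiff(nb[[j]], k); nl <- setdiff(nb[[k]], j)
    if (length(ni) && length(nl)) {
      i <- ni[1L]; l <- nl[1L]
      if (i != l) dihedrals[[length(dihedrals) + 1L]] <- c(i, j, k, l)
    }
  }
  dihedrals <- if (length(dihedrals)) as.data.frame(do.call(rbind, dihedrals)) else
    data.frame(V1 = integer(), V2 = integer(), V3 = integer(), V4 = integer())
  names(dihedrals) <- c("i", "j", "k", "l")
  if (nrow(dihedrals)) {
    dp <- t(mapply(function(j, k) unlist(.lookup_dihedral(params, type[j], type[k])),
                   dihedrals$j, dihedrals$k))
    dihedrals$phis <- dp[, 1]; dihedrals$n <- dp[, 2]; dihedrals$kp <- dp[, 3]
  } else { dihedrals$phis <- numeric(); dihedrals$n <- integer(); dihedrals$kp <- numeric() }

  # impropers: keep every 3-coordinated sp2 center planar (center is the
  # second atom of the i-j-k-l out-of-plane dihedral)
  impd <- params$impropertypes
  impropers <- list()
  for (j in seq_len(n)) {
    if (type[j] %in% impd$sp2_types && length(nb[[j]]) == 3L) {
      s <- nb[[j]]
      impropers[[length(impropers) + 1L]] <- c(s[1L], j, s[2L], s[3L])
    }
  }
  impropers <- if (length(impropers)) as.data.frame(do.call(rbind, impropers)) else
    data.frame(V1 = integer(), V2 = integer(), V3 = integer(), V4 = integer())
  names(impropers) <- c("i", "j", "k", "l")
  impropers$xi0 <- rep(impd$xi0, nrow(impropers))
  impropers$kxi <- rep(impd$kxi, nrow(impropers))

  # exclusions: graph distance 1 or 2 exactly
  excl <- unique(rbind(
    cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)),
    if (nrow(angles)) cbind(pmin(angles$i, angles$k), pmax(angles$i, angles$k))))
  excl_key <- if (is.null(excl)) character() else paste(excl[, 1], excl[, 2])

  # nonbonded pair list: all pairs minus exclusions (1-4 at full strength)
  if (n >= 2L) {
    allp <- utils::combn(n, 2L)
    keep <- !(paste(allp[1, ], allp[2, ]) %in% excl_key)
    pi <- allp[1, keep]; pj <- allp[2, keep]
  } else { pi <- integer(); pj <- integer() }
  si <- params$atomtypes$sigma[match(type, params$atomtypes$type)]
  ei <- params$atomtypes$epsilon[match(type, params$atomtypes$type)]
  pairs <- data.frame(i = pi, j = pj,
                      sigma = (si[pi] + si[pj]) / 2,
                      epsilon = sqrt(ei[pi] * ei[pj]),
                      qq = charge[pi] * charge[pj])
  # third neighbours (graph distance exactly 3) get softened LJ
  if (nrow(pairs)) {
    d3 <- character()
    for (a in seq_len(n)) {
      d1 <- nb[[a]]
      d2 <- setdiff(unique(unlist(nb[d1])), c(a, d1))
      d3a <- setdiff(unique(unlist(nb[d2])), c(a, d1, d2))
      d3a <- d3a[d3a > a]
      if (length(d3a)) d3 <- c(d3, paste(a, d3a))
    }
    is14 <- paste(pairs$i, pairs$j) %in% d3
    pairs$sigma[is14] <- pairs$sigma[is14] * params$pairs14$sigma_scale
    pairs$epsilon[is14] <- pairs$epsilon[is14] * params$pairs14$eps_scale
    pairs$is14 <- is14
  } else pairs$is14 <- logical()

  atoms <- data.frame(name = atoms_df$name, type = type, charge = charge,
                      mass = mass, res_id = idx,
                      res_name = atoms_df$res_name,
                      res_seq = atoms_df$res_seq,
                      chain_id = atoms_df$chain_id, stringsAsFactors = FALSE)
  used <- params$atomtypes[params$atomtypes$type %in% unique(type), , drop = FALSE]
  rownames(used) <- NULL
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, impropers = impropers, pairs = pairs,
                 exclusions = data.frame(i = excl[, 1], j = excl[, 2]),
                 flavour = flavour, type_table = used,
                 epsilon_r = params$epsilon_r),
            class = "ptm_topology")
}

#' @export
print.ptm_topology <- function(x, ...) {
  cat(sprintf("ptm_topology (%s): %d atoms, %d bonds, %d angles, %d dihedrals, %d nonbonded pairs, %d exclusions\n",
              x$flavour, nrow(x$atoms), nrow(x$bonds), nrow(x$angles),
              nrow(x$dihedrals), nrow(x$pairs), nrow(x$exclusions)))
  invisible(x)
}

# accumulate per-term force contributions onto per-atom rows
.acc_force <- function(f, idx, contrib) {
  if (length(idx) == 0L) return(f)
  for (d in 1:3) {
    s <- rowsum(contrib[, d], idx)
    rows <- as.integer(rownames(s))
    f[rows, d] <- f[rows, d] + s[, 1]
  }
  f
}

.row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Evaluate energy and forces
#'
#' @param positions N x 3 matrix of coordinates, nm.
#' @param topology a `ptm_topology`.
#' @param cutoff nonbonded cutoff, nm; Lennard-Jones and Coulomb
#'   interactions beyond it contribute exactly zero (plain truncation).
#' @return a `ptm_energy`: list with `total`, per-term breakdown (`bond`,
#'   `angle`, `dihedral`, `lj`, `coulomb`) in kJ/mol, and `forces`
#'   (N x 3, kJ/mol/nm), the exact negative gradient.
#' @export
energy_forces <- function(positions, topology, cutoff = 1.4) {
  x <- as.matrix(positions)
  n <- nrow(topology$atoms)
  if (nrow(x) != n || ncol(x) != 3L)
    stop(sprintf("positions must be a %d x 3 matrix", n))
  if (!all(is.finite(x))) stop("non-finite positions")
  if (cutoff <= 0) stop("cutoff must be positive")
  f <- matrix(0, n, 3)
  e_bond <- e_angle <- e_dih <- e_lj <- e_coul <- 0

  bd <- topology$bonds
  if (nrow(bd)) {
    dv <- x[bd$i, , drop = FALSE] - x[bd$j, , drop = FALSE]
    r <- sqrt(rowSums(dv * dv))
    if (any(r < 1e-6)) stop("singularity: coincident bonded atoms")
    diff <- r - bd$b0
    e_bond <- sum(0.5 * bd$kb * diff^2)
    fi <- -(bd$kb * diff / r) * dv
    f <- .acc_force(f, bd$i, fi)
    f <- .acc_force(f, bd$j, -fi)
  }

  an <- topology$angles
  if (nrow(an)) {
    u <- x[an$i, , drop = FALSE] - x[an$j, , drop = FALSE]
    v <- x[an$k, , drop = FALSE] - x[an$j, , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    cth <- rowSums(u * v) / (nu * nv)
    cth <- pmax(-1, pmin(1, cth))
    th <- acos(cth)
    sth <- sqrt(pmax(1 - cth^2, 1e-12))
    th0 <- .deg2rad(an$theta0)
    e_angle <- sum(0.5 * an$kt * (th - th0)^2)
    dEdth <- an$kt * (th - th0)
    # dcos(theta)/dri and /drk; dtheta = -dcos/sin
    dci <- (v / (nu * nv)) - (cth / nu^2) * u
    dck <- (u / (nu * nv)) - (cth / nv^2) * v
    fi <- (dEdth / sth) * dci
    fk <- (dEdth / sth) * dck
    f <- .acc_force(f, an$i, fi)
    f <- .acc_force(f, an$k, fk)
    f <- .acc_force(f, an$j, -(fi + fk))
  }

  e_improper <- 0
  torsion_term <- function(dh, dEdphi_of) {
    # returns energy contribution via dEdphi_of(phi) -> list(e, dEdphi)
    b1 <- x[dh$j, , drop = FALSE] - x[dh$i, , drop = FALSE]
    b2 <- x[dh$k, , drop = FALSE] - x[dh$j, , drop = FALSE]
    b3 <- x[dh$l, , drop = FALSE] - x[dh$k, , drop = FALSE]
    m <- .row_cross(b1, b2)
    nn <- .row_cross(b2, b3)
    nb2 <- sqrt(rowSums(b2 * b2))
    m2 <- rowSums(m * m); n2 <- rowSums(nn * nn)
    phi <- atan2(rowSums(.row_cross(m, nn) * b2) / nb2, rowSums(m * nn))
    ed <- dEdphi_of(phi)
    # standard rigid-rotation force distribution about the j-k bond
    fi <- (ed$dEdphi * nb2 / m2) * m
    fl <- -(ed$dEdphi * nb2 / n2) * nn
    p <- rowSums(b1 * b2) / nb2^2
    q <- rowSums(b3 * b2) / nb2^2
    sv <- p * fi - q * fl
    f <<- .acc_force(f, dh$i, fi)
    f <<- .acc_force(f, dh$j, -sv - fi)
    f <<- .acc_force(f, dh$k, sv - fl)
    f <<- .acc_force(f, dh$l, fl)
    ed$e
  }

  dh <- topology$dihedrals
  if (nrow(dh)) {
    e_dih <- torsion_term(dh, function(phi) {
      phis <- .deg2rad(dh$phis)
      list(e = sum(dh$kp * (1 + cos(dh$n * phi - phis))),
           dEdphi = -dh$kp * dh$n * sin(dh$n * phi - phis))
    })
  }
  im <- topology$impropers
  if (!is.null(im) && nrow(im)) {
    e_improper <- torsion_term(im, function(phi) {
      d <- phi - .deg2rad(im$xi0)
      d <- ((d + pi) %% (2 * pi)) - pi
      list(e = sum(0.5 * im$kxi * d^2), dEdphi = im$kxi * d)
    })
  }
  pr <- topology$pairs
  if (nrow(pr)) {
    dv <- x[pr$i, , drop = FALSE] - x[pr$j, , drop = FALSE]
    r2 <- rowSums(dv * dv)
    keep <- r2 < cutoff^2
    if (any(keep)) {
      dv <- dv[keep, , drop = FALSE]
      r2 <- r2[keep]
      sig <- pr$sigma[keep]; eps <- pr$epsilon[keep]; qq <- pr$qq[keep]
      ii <- pr$i[keep]; jj <- pr$j[keep]
      sr2 <- sig^2 / r2
      sr6 <- sr2^3
      e_lj <- sum(4 * eps * (sr6^2 - sr6))
      r1 <- sqrt(r2)
      ke <- .COULOMB_K / (topology$epsilon_r %||% 1)
      e_coul <- sum(ke * qq / r1)
      # dE/dr / r, so that F_i = -(dE/dr)/r * dv
      glj <- (24 * eps / r2) * (2 * sr6^2 - sr6)
      gcoul <- ke * qq / (r2 * r1)
      fi <- (glj + gcoul) * dv
      f <- .acc_force(f, ii, fi)
      f <- .acc_force(f, jj, -fi)
    }
  }

  total <- e_bond + e_angle + e_dih + e_improper + e_lj + e_coul
  structure(list(total = total, bond = e_bond, angle = e_angle,
                 dihedral = e_dih, improper = e_improper, lj = e_lj,
                 coulomb = e_coul, forces = f),
            class = "ptm_energy")
}

#' @export
print.ptm_energy <- function(x, ...) {
  cat(sprintf(
    "E = %.4f kJ/mol (bond %.4f, angle %.4f, dihedral %.4f, improper %.4f, LJ %.4f, Coulomb %.4f); fmax = %.4g kJ/mol/nm\n",
    x$total, x$bond, x$angle, x$dihedral, x$improper, x$lj, x$coulomb,
    max(sqrt(rowSums(x$forces^2)))))
  invisible(x)
}
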