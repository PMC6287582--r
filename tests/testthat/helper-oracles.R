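# Independent brute-force oracles and random-fixture generators. Everything
# here is deliberately written from first principles (plain loops, its own
# trigonometry) so that agreement with the package is a genuine two-route
# check.

o_dist <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2)

o_angle <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

o_dihedral <- function(a, b, c_, d) {
  u1 <- b - a; u2 <- c_ - b; u3 <- d - c_
  cr12 <- c(u1[2] * u2[3] - u1[3] * u2[2], u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  cr23 <- c(u2[2] * u3[3] - u2[3] * u3[2], u2[3] * u3[1] - u2[1] * u3[3],
            u2[1] * u3[2] - u2[2] * u3[1])
  y <- sum(u1 * cr23) * sqrt(sum(u2^2))
  x <- sum(cr12 * cr23)
  atan2(y, x) * 180 / pi
}

# best-fit plane normal via SVD (independent of the package's eigen route)
o_plane_normal <- function(coords) {
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  sv$v[, 3]
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# --- random mixed-residue fixture ------------------------------------------

.helper_frags <- list(
  ALA = data.frame(name = "CA", element = "C",
                   x = 0, y = 0, z = 0, stringsAsFactors = FALSE),
  SER = data.frame(name = c("CA", "OG", "HG1"), element = c("C", "O", "H"),
                   x = c(0, 1.4, 2.0), y = c(0, 0, 0.7), z = 0,
                   stringsAsFactors = FALSE),
  LYS = data.frame(name = c("CA", "CE", "NZ", "HZ1"),
                   element = c("C", "C", "N", "H"),
                   x = c(0, 1.5, 2.9, 3.4), y = c(0, 0, 0.7, 1.5), z = 0,
                   stringsAsFactors = FALSE),
  GLU = data.frame(name = c("CA", "CD", "OE1", "OE2"),
                   element = c("C", "C", "O", "O"),
                   x = c(0, 1.6, 2.6, 2.6), y = c(0, 0, 0.9, -0.9), z = 0,
                   stringsAsFactors = FALSE),
  ASP = data.frame(name = c("CA", "CG", "OD1", "OD2"),
                   element = c("C", "C", "O", "O"),
                   x = c(0, 1.5, 2.5, 2.5), y = c(0, 0, 0.9, -0.9), z = 0,
                   stringsAsFactors = FALSE),
  CYS = data.frame(name = c("CA", "CB", "SG"), element = c("C", "C", "S"),
                   x = c(0, 1.5, 2.3), y = c(0, 0, 1.2), z = 0,
                   stringsAsFactors = FALSE),
  ARG = data.frame(name = c("CA", "CD", "NE", "CZ", "NH1", "NH2"),
                   element = c("C", "C", "N", "C", "N", "N"),
                   x = c(0, 1.5, 2.6, 3.9, 4.6, 4.6),
                   y = c(0, 0, 0.4, 0.4, 1.5, -0.7), z = 0,
                   stringsAsFactors = FALSE),
  PHE = local({
    th <- seq(0, by = pi / 3, length.out = 6)
    data.frame(name = c("CA", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
               element = "C",
               x = c(0, 1.39 * cos(th)), y = c(0, 1.39 * sin(th)),
               z = c(-2.5, rep(0, 6)), stringsAsFactors = FALSE)
  }),
  HSD = local({
    th <- seq(pi / 2, by = 2 * pi / 5, length.out = 5)
    data.frame(name = c("CA", "CG", "ND1", "CE1", "NE2", "CD2"),
               element = c("C", "C", "N", "C", "N", "C"),
               x = c(0, 1.16 * cos(th)), y = c(0, 1.16 * sin(th)),
               z = c(-2.2, rep(0, 5)), stringsAsFactors = FALSE)
  }),
  HSP = data.frame(name = c("CA", "CG", "ND1", "NE2"),
                   element = c("C", "C", "N", "N"),
                   x = c(0, 1.3, 2.1, 2.8), y = c(0, 0, 1.0, -0.4), z = 0,
                   stringsAsFactors = FALSE)
)

# n residues of mixed chemistry on a jittered grid, randomly oriented; with
# random charges and LJ parameters so the energy detectors are exercised
random_system <- function(n = 30, seed = 1, spacing = 6.5, n_chains = 1) {
  set.seed(seed)
  kinds <- sample(names(.helper_frags), n, replace = TRUE)
  side <- ceiling(n^(1 / 3))
  rows <- list()
  serial <- 1L
  for (i in seq_len(n)) {
    f <- .helper_frags[[kinds[i]]]
    rot <- random_rotation()
    xyz <- as.matrix(f[, c("x", "y", "z")]) %*% t(rot)
    gx <- ((i - 1) %% side)
    gy <- ((i - 1) %/% side) %% side
    gz <- (i - 1) %/% (side * side)
    ctr <- spacing * c(gx, gy, gz) + runif(3, -1, 1)
    chain <- LETTERS[((i - 1) %% n_chains) + 1]
    rows[[i]] <- data.frame(
      serial = seq(serial, length.out = nrow(f)),
      name = f$name, element = f$element, resname = kinds[i],
      resno = i * 2L, chain = chain, insert = "",
      charge = round(runif(nrow(f), -0.8, 0.8), 3),
      lj_epsilon = round(runif(nrow(f), 0.02, 0.3), 4),
      lj_rmin_half = round(runif(nrow(f), 1.3, 2.2), 4),
      x = xyz[, 1] + ctr[1], y = xyz[, 2] + ctr[2], z = xyz[, 3] + ctr[3],
      stringsAsFactors = FALSE
    )
    serial <- serial + nrow(f)
  }
  atoms <- do.call(rbind, rows)
  ord <- order(atoms$chain, atoms$resno)
  atoms <- atoms[ord, , drop = FALSE]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  molecular_system(atoms[, setdiff(names(atoms), c("x", "y", "z"))],
                   list(xyz))
}

# --- per-detector oracles (exhaustive enumeration) -------------------------

res_atoms <- function(sys, r) sys$residues$first[r]:sys$residues$last[r]

res_atom <- function(sys, r, nm) {
  span <- res_atoms(sys, r)
  span[sys$atoms$name[span] == nm][1]
}

oracle_calpha <- function(sys, crit) {
  res <- sys$residues
  xyz <- sys$frames[[1]]
  out <- character(0)
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      ca_i <- res_atom(sys, i, "CA"); ca_j <- res_atom(sys, j, "CA")
      if (is.na(ca_i) || is.na(ca_j)) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) <= crit$seq_exclusion_calpha) next
      if (o_dist(xyz[ca_i, ], xyz[ca_j, ]) <= crit$calpha_d) {
        out <- c(out, paste(i, j))
      }
    }
  }
  sort(out)
}

oracle_hbonds <- function(sys, crit) {
  at <- sys$atoms
  xyz <- sys$frames[[1]]
  rid <- rep(seq_len(nrow(sys$residues)),
             sys$residues$last - sys$residues$first + 1)
  # pair each H to the nearest same-residue heavy atom within 1.25 A
  hpart <- rep(NA_integer_, nrow(at))
  for (h in which(at$element == "H")) {
    best <- NA; bd <- 1.25
    for (j in which(at$element != "H" & rid == rid[h])) {
      dd <- o_dist(xyz[h, ], xyz[j, ])
      if (dd <= bd) { bd <- dd; best <- j }
    }
    hpart[h] <- best
  }
  has_h <- rep(FALSE, nrow(at))
  has_h[stats::na.omit(hpart)] <- TRUE
  out <- character(0)
  for (h in which(!is.na(hpart))) {
    d_at <- hpart[h]
    if (!(at$element[d_at] %in% c("N", "O", "S"))) next
    for (a_at in seq_len(nrow(at))) {
      ok <- at$element[a_at] == "O" ||
        (at$element[a_at] == "N" && !has_h[a_at]) ||
        (at$element[a_at] == "S" && at$resname[a_at] %in% c("MET", "CYS"))
      if (!ok || rid[a_at] == rid[d_at]) next
      if (o_dist(xyz[d_at, ], xyz[a_at, ]) > crit$hb_d) next
      ang <- o_angle(xyz[d_at, ] - xyz[h, ], xyz[a_at, ] - xyz[h, ])
      if (ang >= crit$hb_angle_min) {
        out <- c(out, paste(rid[d_at], rid[a_at], at$name[d_at],
                            at$name[h], at$name[a_at]))
      }
    }
  }
  sort(out)
}

oracle_salt_bridges <- function(sys, crit) {
  res <- sys$residues
  at <- sys$atoms
  xyz <- sys$frames[[1]]
  basic <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                HSP = c("ND1", "NE2"))
  acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  out <- character(0)
  for (b in seq_len(nrow(res))) {
    bn <- basic[[res$resname[b]]]
    if (is.null(bn)) next
    for (a in seq_len(nrow(res))) {
      an <- acidic[[res$resname[a]]]
      if (is.null(an)) next
      dmin <- Inf
      for (n1 in bn) {
        for (o1 in an) {
          ni <- res_atom(sys, b, n1); oi <- res_atom(sys, a, o1)
          if (is.na(ni) || is.na(oi)) next
          dmin <- min(dmin, o_dist(xyz[ni, ], xyz[oi, ]))
        }
      }
      if (dmin <= crit$sb_d) out <- c(out, paste(min(a, b), max(a, b)))
    }
  }
  sort(unique(out))
}

oracle_disulfides <- function(sys, crit) {
  res <- sys$residues
  xyz <- sys$frames[[1]]
  cys <- which(res$resname == "CYS")
  out <- character(0)
  for (i in cys) {
    for (j in cys) {
      if (j <= i) next
      sgi <- res_atom(sys, i, "SG"); sgj <- res_atom(sys, j, "SG")
      cbi <- res_atom(sys, i, "CB"); cbj <- res_atom(sys, j, "CB")
      if (anyNA(c(sgi, sgj, cbi, cbj))) next
      if (o_dist(xyz[sgi, ], xyz[sgj, ]) > crit$ss_d) next
      chi <- abs(o_dihedral(xyz[cbi, ], xyz[sgi, ], xyz[sgj, ], xyz[cbj, ]))
      if (chi >= crit$ss_dihedral_lo && chi <= crit$ss_dihedral_hi) {
        out <- c(out, paste(i, j))
      }
    }
  }
  sort(out)
}

oracle_rings <- function(sys) {
  res <- sys$residues
  xyz <- sys$frames[[1]]
  ring_names <- list(
    PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HSD = c("CG", "ND1", "CD2", "CE1", "NE2"),
    HSE = c("CG", "ND1", "CD2", "CE1", "NE2")
  )
  out <- list()
  for (r in seq_len(nrow(res))) {
    nm <- ring_names[[res$resname[r]]]
    if (is.null(nm)) next
    idx <- vapply(nm, function(x) res_atom(sys, r, x), integer(1))
    if (anyNA(idx)) next
    coords <- xyz[idx, , drop = FALSE]
    out[[length(out) + 1]] <- list(residue = r, centroid = colMeans(coords),
                                   normal = o_plane_normal(coords))
  }
  out
}

oracle_pi_pi <- function(sys, crit) {
  rings <- oracle_rings(sys)
  out <- character(0)
  if (length(rings) < 2) return(out)
  for (a in seq_along(rings)) {
    for (b in seq_along(rings)) {
      if (b <= a) next
      if (o_dist(rings[[a]]$centroid, rings[[b]]$centroid) <= crit$pipi_d) {
        i <- min(rings[[a]]$residue, rings[[b]]$residue)
        j <- max(rings[[a]]$residue, rings[[b]]$residue)
        out <- c(out, paste(i, j))
      }
    }
  }
  sort(out)
}

oracle_cation_pi <- function(sys, crit) {
  res <- sys$residues
  xyz <- sys$frames[[1]]
  rings <- oracle_rings(sys)
  cats <- list()
  for (r in seq_len(nrow(res))) {
    rn <- res$resname[r]
    if (rn == "ARG") {
      i <- res_atom(sys, r, "CZ")
      if (!is.na(i)) cats[[length(cats) + 1]] <- list(residue = r, p = xyz[i, ])
    } else if (rn == "LYS") {
      i <- res_atom(sys, r, "NZ")
      if (!is.na(i)) cats[[length(cats) + 1]] <- list(residue = r, p = xyz[i, ])
    } else if (rn == "HSP") {
      i1 <- res_atom(sys, r, "ND1"); i2 <- res_atom(sys, r, "NE2")
      if (!anyNA(c(i1, i2))) cats[[length(cats) + 1]] <-
          list(residue = r, p = (xyz[i1, ] + xyz[i2, ]) / 2)
    }
  }
  out <- character(0)
  for (rg in rings) {
    for (ct in cats) {
      if (rg$residue == ct$residue) next
      if (o_dist(rg$centroid, ct$p) > crit$catpi_d) next
      ang <- o_angle(rg$normal, ct$p - rg$centroid)
      if ((ang >= 0 && ang <= 60) || (ang >= 120 && ang <= 180)) {
        i <- min(rg$residue, ct$residue); j <- max(rg$residue, ct$residue)
        out <- c(out, paste(i, j))
      }
    }
  }
  sort(unique(out))
}

oracle_arg_arg <- function(sys, crit) {
  res <- sys$residues
  xyz <- sys$frames[[1]]
  args <- which(res$resname == "ARG")
  out <- character(0)
  for (a in args) {
    for (b in args) {
      if (b <= a) next
      ia <- vapply(c("CZ", "NH1", "NH2", "NE"),
                   function(x) res_atom(sys, a, x), integer(1))
      ib <- vapply(c("CZ", "NH1", "NH2", "NE"),
                   function(x) res_atom(sys, b, x), integer(1))
      if (anyNA(ia) || anyNA(ib)) next
      ca <- colMeans(xyz[ia, , drop = FALSE])
      cb <- colMeans(xyz[ib, , drop = FALSE])
      if (o_dist(ca, cb) <= crit$argarg_d) out <- c(out, paste(a, b))
    }
  }
  sort(out)
}

# naive double-loop residue-pair Coulomb and LJ sums (bonded-neighbour
# residue pairs excluded by the same resno-adjacency rule)
oracle_pair_energy <- function(sys, i, j, crit) {
  at <- sys$atoms
  xyz <- sys$frames[[1]]
  ec <- 0; ev <- 0
  for (a in res_atoms(sys, i)) {
    for (b in res_atoms(sys, j)) {
      r <- o_dist(xyz[a, ], xyz[b, ])
      if (r > crit$coulomb_cutoff) next
      ec <- ec + 332.0636 * at$charge[a] * at$charge[b] / (crit$dielectric * r)
      eps <- sqrt(at$lj_epsilon[a] * at$lj_epsilon[b])
      rmin <- at$lj_rmin_half[a] + at$lj_rmin_half[b]
      ev <- ev + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  c(coulomb = ec, vdw = ev)
}

oracle_energy_edges <- function(sys, crit) {
  res <- sys$residues
  coul <- character(0); vdw <- character(0)
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$resno[i] - res$resno[j]) <= 1) next
      e <- oracle_pair_energy(sys, i, j, crit)
      if (abs(e["coulomb"]) >= crit$coulomb_energy_thr) {
        coul <- c(coul, paste(i, j))
      }
      if (e["vdw"] <= crit$vdw_energy_thr) vdw <- c(vdw, paste(i, j))
    }
  }
  list(coulomb = sort(coul), vdw = sort(vdw))
}

# textbook centrality formulas on a small simple graph given as an edge list
oracle_centralities <- function(n, edges, weights = rep(1, nrow(edges))) {
  adj <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- weights[k]
    adj[edges[k, 2], edges[k, 1]] <- weights[k]
  }
  reach <- (adj > 0) * 1
  # BFS shortest-path distances and path counts (Brandes-style sigma)
  dist_m <- matrix(Inf, n, n); diag(dist_m) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  for (s in seq_len(n)) {
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(reach[v, ] > 0)) {
          if (is.infinite(dist_m[s, w])) {
            dist_m[s, w] <- dist_m[s, v] + 1
            nxt <- c(nxt, w)
          }
          if (dist_m[s, w] == dist_m[s, v] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.infinite(dist_m[s, t])) next
        if (dist_m[s, v] + dist_m[v, t] == dist_m[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  cls <- vapply(seq_len(n), function(v) {
    d <- dist_m[v, ]
    inside <- which(is.finite(d) & seq_len(n) != v)
    if (length(inside) == 0) return(NA_real_)
    length(inside) / sum(d[inside])
  }, numeric(1))
  # power iteration for the principal eigenvector
  v <- rep(1, n)
  for (it in 1:500) v <- adj %*% v / max(adj %*% v)
  list(
    degree = rowSums(reach),
    weighted_degree = rowSums(adj),
    betweenness = btw,
    closeness = cls,
    eigenvector = as.numeric(v)
  )
}

o_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

residue_pair_energies_for_test <- function(sys, crit) {
  rinmd:::residue_pair_energies(sys, 1, crit)
}

# restrict a system to the atoms of the given residues (test plumbing)
subset_residues_for_test <- function(sys, residues) {
  idx <- unlist(lapply(residues, function(r) res_atoms(sys, r)))
  atoms <- sys$atoms[idx, , drop = FALSE]
  frames <- lapply(sys$frames, function(fr) fr[idx, , drop = FALSE])
  molecular_system(atoms, frames)
}

# apply a rigid transform to every frame of a system
transform_system <- function(sys, rot, shift) {
  sys$frames <- lapply(sys$frames, function(fr) {
    sweep(fr %*% t(rot), 2, -shift)
  })
  sys
}
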