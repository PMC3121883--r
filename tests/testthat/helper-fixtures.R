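# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own code paths: plain-arithmetic RMSD, quaternion-parameterised
# rigid-fit optimisation, and an exhaustive implementation of the greedy
# max-neighbor clustering rule.

tiny_topology <- function(n_res = 3, chain = "P") {
  atom_topology(name = rep(c("N", "CA", "C"), n_res),
                residue_name = rep("ALA", 3 * n_res),
                residue_id = rep(seq_len(n_res), each = 3),
                chain_id = rep(chain, 3 * n_res))
}

random_frame <- function(n_atoms, scale = 10) {
  matrix(runif(n_atoms * 3, -scale, scale), n_atoms, 3)
}

rotation_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# plain-arithmetic RMSD, no superposition
oracle_rmsd_raw <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sqrt(sum((a - b)^2) / nrow(a))
}

# independent rigid-superposition oracle: minimise RMSD over a unit
# quaternion + translation with general-purpose optimisation (multi-start
# Nelder-Mead refined by BFGS); never touches the SVD path under test
oracle_fit_rmsd <- function(mobile, reference) {
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); Rf <- sweep(reference, 2, cr)
  obj <- function(q) {
    moved <- M %*% t(quat_rot(q))
    sqrt(mean(rowSums((moved - Rf)^2)))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(c(1, 0, 0, 0),
                  matrix(rnorm(4 * 12), 12, 4))
  for (s in seq_len(nrow(starts))) {
    r1 <- optim(starts[s, ], obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    r2 <- optim(r1$par, obj, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, r1$value, r2$value)
  }
  best
}

# exhaustive implementation of the greedy max-neighbor clustering rule with
# the lowest-index tie-break, written as directly as possible
oracle_gromos <- function(d, cutoff) {
  n <- nrow(d)
  assigned <- rep(FALSE, n)
  labels <- integer(n)
  centers <- integer(0)
  cl <- 0L
  while (!all(assigned)) {
    best_count <- -1L; best_i <- NA_integer_
    for (i in which(!assigned)) {
      cnt <- 0L
      for (j in which(!assigned))
        if (j != i && d[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best_count) { best_count <- cnt; best_i <- i }
    }
    cl <- cl + 1L
    centers[cl] <- best_i
    for (j in which(!assigned))
      if (j == best_i || d[best_i, j] <= cutoff) {
        labels[j] <- cl
        assigned[j] <- TRUE
      }
  }
  sizes <- tabulate(labels, cl)
  ord <- order(-sizes, centers)
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  list(labels = relabel[labels], centers = centers[ord], sizes = sizes[ord])
}

# random symmetric distance matrix from points in 3-space (a true metric)
random_distance_matrix <- function(n, scale = 3) {
  pts <- matrix(runif(n * 3, 0, scale), n, 3)
  as.matrix(dist(pts))
}

write_text_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}
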