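# Shared fixtures, generated in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

fix_complex <- function() memo("cx", function()
  make_toy_complex(c(H = "AKYWSDE", A = "TNLERYQ"), "H", "A",
                   approach = 4.5, seed = 1))

fix_panel <- function() memo("panel", function() toy_complex_panel(1))

# medium synthetic dataset shared by model-level unit tests
fix_sim <- function() memo("sim", function()
  make_synthetic_dataset(fix_panel(), n_records = 120, sigma = 0.3, seed = 11))

# a single-atom "complex" helper for geometric edge cases
atom_pair_complex <- function(d, element = "C", atom = "CB", resname = "ALA") {
  as_complex(tibble::tibble(
    chain = c("H", "A"), resno = 1L, icode = "", resname = resname,
    atom = atom, element = element, x = c(0, d), y = 0, z = 0
  ), "H", "A")
}

# random 50-atom single-chain fixture for signature oracles
random_atom_cloud <- function(seed, n = 50) {
  set.seed(seed)
  tab <- pharmacophore_table()
  rows <- tab[sample(nrow(tab), n, replace = TRUE), ]
  as_complex(tibble::tibble(
    chain = rep(c("H", "A"), length.out = n),
    resno = seq_len(n), icode = "", resname = rows$resname,
    atom = rows$atom, element = abddg:::atom_element(rows$atom),
    x = runif(n, 0, 15), y = runif(n, 0, 15), z = runif(n, 0, 15)
  ), "H", "A")
}

# brute-force O(n^2) signature recount, independent of csm_signature
brute_signature <- function(complex, sites, params, tab = pharmacophore_table()) {
  xyz <- cbind(complex$x, complex$y, complex$z)
  site_idx <- which(complex$key %in% sites)
  near <- which(vapply(seq_len(nrow(xyz)), function(i)
    min(sqrt(colSums((t(xyz[site_idx, , drop = FALSE]) - xyz[i, ])^2))), 0) <=
      params$environment_radius)
  classes <- lapply(near, function(i)
    atom_classes(complex$resname[i], complex$atom[i], tab))
  out <- numeric()
  pcl <- abddg:::PHARM_CLASSES
  for (a in pcl) for (b in pcl) {
    if (match(a, pcl) > match(b, pcl)) next
    for (e in params$edges) {
      cnt <- 0
      for (i in seq_along(near)) for (j in seq_along(near)) {
        if (i >= j) next
        d <- sqrt(sum((xyz[near[i], ] - xyz[near[j], ])^2))
        if (d < params$d_min || d > e) next
        if ((a %in% classes[[i]] && b %in% classes[[j]]) ||
            (b %in% classes[[i]] && a %in% classes[[j]])) cnt <- cnt + 1
      }
      out[sprintf("sig.%s:%s.%g", a, b, e)] <- cnt
    }
  }
  out
}

rotate_complex <- function(complex, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  m <- cbind(complex$x, complex$y, complex$z) %*% t(q)
  complex$x <- m[, 1] + 5; complex$y <- m[, 2] - 2; complex$z <- m[, 3] + 1
  complex
}
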