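# Synthetic structures and affinity datasets with known ground truth, so the
# whole pipeline (parsing, curation, featurization, training, evaluation) is
# exercisable offline. Toy complexes are ideal-geometry extended chains; they
# emulate the tabular/geometric properties of real complexes, not their folds.

#' Build a synthetic two-sided complex with ideal geometry
#'
#' Each chain is an extended backbone (phi = -140, psi = 135, omega = 180)
#' with idealized template side chains. The antigen partition is translated
#' so that the minimum heavy-atom approach distance between the two sides
#' equals `approach` (within 0.1 Angstrom). Deterministic given `seed`.
#'
#' @param chains Named character vector of one-letter sequences, e.g.
#'   `c(H = "AKYWSDE", A = "TNLERYQ")`. Sequences must have length >= 5.
#' @param antibody_chains,antigen_chains Chain IDs forming the partition.
#' @param approach Requested minimum heavy-atom distance between the two
#'   sides, Angstrom. Must be >= 2 (smaller would clash).
#' @param seed Integer seed controlling the small rigid jitter applied to
#'   the antigen side.
#' @param pdb_path Optional path; when given the complex is also written as
#'   a PDB file.
#' @return An [as_complex()] tibble.
#' @export
make_toy_complex <- function(chains, antibody_chains, antigen_chains,
                             approach = 4.5, seed = 1, pdb_path = NULL) {
  if (any(nchar(chains) < 5)) stop("chain sequences must have length >= 5")
  if (approach < 2) stop("clashing placement request: approach < 2 Angstrom")
  antibody_chains <- split_chains(antibody_chains)
  antigen_chains <- split_chains(antigen_chains)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  build_side <- function(ids) {
    purrr::imap_dfr(ids, function(id, k) {
      ch <- build_extended_chain(chains[[id]], id)
      ch$z <- ch$z + 7 * (k - 1)  # side-by-side stacking of same-side chains
      ch
    })
  }
  ab <- build_side(antibody_chains)
  ag <- build_side(antigen_chains)

  # seeded small jitter: shift along x and rotation about y
  rot <- rot_y(stats::runif(1, -10, 10) * pi / 180)
  m <- coords_matrix(ag) %*% t(rot)
  m[, 1] <- m[, 1] + stats::runif(1, -2, 2)
  xab <- coords_matrix(ab)
  gap <- function(t) min(cross_dist(xab, sweep(m, 2, c(0, t, 0), `+`))) - approach
  t0 <- stats::uniroot(gap, c(0.1, 80), tol = 1e-4)$root
  ag$x <- m[, 1]; ag$y <- m[, 2] + t0; ag$z <- m[, 3]

  cx <- as_complex(dplyr::bind_rows(ab, ag),
                   paste(antibody_chains, collapse = ","),
                   paste(antigen_chains, collapse = ","))
  if (!is.null(pdb_path)) write_pdb(cx, pdb_path)
  cx
}

rot_y <- function(a) {
  cbind(c(cos(a), 0, -sin(a)), c(0, 1, 0), c(sin(a), 0, cos(a)))
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Extended-conformation chain with template side chains; heavy atoms only.
build_extended_chain <- function(sequence, chain_id,
                                 phi = -140, psi = 135, omega = 180) {
  aa <- strsplit(sequence, "")[[1]]
  res3 <- aa_three(aa)
  n_res <- length(aa)
  # backbone trace
  n_xyz <- ca <- cc <- vector("list", n_res)
  n_xyz[[1]] <- c(0, 0, 0)
  ca[[1]] <- c(1.458, 0, 0)
  cc[[1]] <- place_atom(c(-0.5, 1, 0), n_xyz[[1]], ca[[1]], 1.525, 111, phi)
  for (i in seq_len(n_res - 1)) {
    n_xyz[[i + 1]] <- place_atom(n_xyz[[i]], ca[[i]], cc[[i]], 1.329, 116.2, psi)
    ca[[i + 1]] <- place_atom(ca[[i]], cc[[i]], n_xyz[[i + 1]], 1.458, 121.7, omega)
    cc[[i + 1]] <- place_atom(cc[[i]], n_xyz[[i + 1]], ca[[i + 1]], 1.525, 111, phi)
  }
  purrr::map_dfr(seq_len(n_res), function(i) {
    o <- place_atom(n_xyz[[i]], ca[[i]], cc[[i]], 1.231, 120.5, psi - 180)
    bb <- tibble::tibble(
      chain = chain_id, resno = i, icode = "", resname = res3[i],
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = c(n_xyz[[i]][1], ca[[i]][1], cc[[i]][1], o[1]),
      y = c(n_xyz[[i]][2], ca[[i]][2], cc[[i]][2], o[2]),
      z = c(n_xyz[[i]][3], ca[[i]][3], cc[[i]][3], o[3])
    )
    tmpl <- residue_template(res3[i])
    side <- tmpl[!tmpl$atom %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(side) == 0) return(bb)
    tm <- coords_matrix(tmpl); rownames(tm) <- tmpl$atom
    tr <- rigid_transform(tm[c("N", "CA", "C"), ],
                          rbind(n_xyz[[i]], ca[[i]], cc[[i]]))
    sc <- tr(coords_matrix(side))
    dplyr::bind_rows(bb, tibble::tibble(
      chain = chain_id, resno = i, icode = "", resname = res3[i],
      atom = side$atom, element = side$element,
      x = sc[, 1], y = sc[, 2], z = sc[, 3]
    ))
  })
}

#' Generate a synthetic affinity dataset with known ground truth
#'
#' Draws random single- and multi-point mutations on the given toy
#' complexes, computes their real feature vectors, and sets the true ddG to
#' a declared linear-plus-interaction function of five named features plus
#' Gaussian noise. K_D pairs are back-computed from the true ddG at 298 K
#' (wild-type K_D 1e-9 M) so the full curation path is exercised; planted
#' non-binders and planted additive/synergistic multi-records are included.
#' The generated ddG distribution is shifted to the requested mean to mimic
#' the skew of curated antibody affinity data.
#'
#' @param complexes Named list of [make_toy_complex()] objects.
#' @param n_records Number of regular records (>= 10).
#' @param sigma Gaussian noise SD, kcal/mol.
#' @param frac_multi Fraction of records that are double/triple mutations.
#' @param n_non_binders Planted non-binder records.
#' @param n_additive,n_synergistic Planted multi-records whose constituent
#'   singles are present.
#' @param target_mean Mean of the generated true ddG distribution, kcal/mol.
#' @param seed Integer seed; every draw is reproducible from it.
#' @param config A [default_config()].
#' @return List: `records` (curated tibble with `partition`), `features`
#'   (rows aligned with `records`), `truth` (coefficients, feature names,
#'   sigma, seed, per-record true ddG).
#' @export
make_synthetic_dataset <- function(complexes, n_records = 500, sigma = 0.3,
                                   frac_multi = 0.3, n_non_binders = 5,
                                   n_additive = 2, n_synergistic = 2,
                                   target_mean = -1, seed = 1,
                                   config = default_config()) {
  if (n_records < 10) stop("n_records must be at least 10")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  truth_features <- c("pc.hydrophobic", "sasa.site", "ct.vdw.all",
                      "pam30.min", "sig.hydrophobic:hydrophobic.10")
  coefs <- c(0.25, 0.02, 0.08, 0.06, 0.01)
  interaction <- list(features = c("pc.hydrophobic", "pam30.min"), coef = 0.02)

  draw_mutation <- function(cx, n_sites) {
    res <- complex_residues(cx)
    res <- res[!is.na(res$side), , drop = FALSE]
    rows <- res[sample(nrow(res), n_sites), , drop = FALSE]
    wt <- aa_one(rows$resname)
    mt <- vapply(wt, function(w) sample(setdiff(names(AA3), w), 1), "")
    paste(paste0(rows$chain, ".", wt, rows$resno, rows$icode, mt), collapse = ";")
  }

  ids <- names(complexes)
  n_multi <- round(n_records * frac_multi)
  recs <- tibble::tibble(
    complex_id = sample(ids, n_records, replace = TRUE),
    n_sites = c(rep(1L, n_records - n_multi),
                sample(2:3, n_multi, replace = TRUE))[sample(n_records)]
  )
  recs$mutations <- vapply(seq_len(n_records), function(i)
    draw_mutation(complexes[[recs$complex_id[i]]], recs$n_sites[i]), "")
  # de-duplicate (complex, mutation) pairs
  recs <- recs[!duplicated(paste(recs$complex_id, recs$mutations)), , drop = FALSE]

  records <- tibble::tibble(
    complex_id = recs$complex_id, mutations = recs$mutations,
    kd_wt = 1e-9, kd_mut = NA_real_, temperature = 298, ddg = NA_real_,
    is_reverse = FALSE, is_non_binder = FALSE, source = "synthetic"
  )
  features <- featurize_dataset(records, complexes, config)
  signal <- as.matrix(features[truth_features]) %*% coefs +
    interaction$coef * features[[interaction$features[1]]] *
    features[[interaction$features[2]]]
  intercept <- target_mean - mean(signal)
  ddg_true <- as.numeric(intercept + signal + stats::rnorm(nrow(records), 0, sigma))
  records$ddg <- ddg_true
  # back-compute K_D pairs through the thermodynamic relation (Eq. of state
  # for the curation path): ddG = RT ln kd_wt - RT ln kd_mut
  rt <- R_KCAL * records$temperature
  records$kd_mut <- exp(log(records$kd_wt) - records$ddg / rt)
  records$ddg <- NA_real_  # force derivation from K_D on read

  # planted additive / synergistic multi-records from existing singles
  singles <- records[!grepl(";", records$mutations, fixed = TRUE), , drop = FALSE]
  singles$ddg <- ddg_true[!grepl(";", records$mutations, fixed = TRUE)]
  planted <- tibble::tibble()
  plant <- function(kind, n) {
    purrr::map_dfr(seq_len(n), function(i) {
      repeat {
        cid <- sample(unique(singles$complex_id), 1)
        pool <- singles[singles$complex_id == cid, , drop = FALSE]
        if (nrow(pool) < 2) next
        pick <- pool[sample(nrow(pool), 2), , drop = FALSE]
        sites <- sub("^([A-Za-z0-9]\\.[A-Z][0-9]+[A-Z]?)[A-Z]$", "\\1", pick$mutations)
        if (anyDuplicated(sites)) next
        break
      }
      offset <- if (kind == "additive") stats::runif(1, -0.5, 0.5) else
        sample(c(-1, 1), 1) * stats::runif(1, 1.5, 3)
      ddg_multi <- sum(pick$ddg) + offset
      tibble::tibble(
        complex_id = cid, mutations = paste(pick$mutations, collapse = ";"),
        kd_wt = 1e-9, kd_mut = exp(log(1e-9) - ddg_multi / (R_KCAL * 298)),
        temperature = 298, ddg = NA_real_, is_reverse = FALSE,
        is_non_binder = FALSE, source = paste0("planted_", kind)
      )
    })
  }
  planted <- dplyr::bind_rows(plant("additive", n_additive),
                              plant("synergistic", n_synergistic))
  if (nrow(planted) > 0)
    planted <- planted[!duplicated(paste(planted$complex_id, planted$mutations)), ]

  nb <- tibble::tibble()
  if (n_non_binders > 0) {
    nb <- tibble::tibble(
      complex_id = sample(ids, n_non_binders, replace = TRUE),
      mutations = NA_character_, kd_wt = 1e-9, kd_mut = NA_real_,
      temperature = 298, ddg = NA_real_, is_reverse = FALSE,
      is_non_binder = TRUE, source = "synthetic_non_binder"
    )
    nb$mutations <- vapply(seq_len(n_non_binders), function(i)
      draw_mutation(complexes[[nb$complex_id[i]]], sample(2:3, 1)), "")
  }

  all_records <- curate_dataset(dplyr::bind_rows(records, planted, nb))
  extra_feats <- if (nrow(planted) + nrow(nb) > 0)
    featurize_dataset(dplyr::bind_rows(planted, nb), complexes, config) else NULL
  features_all <- dplyr::bind_rows(features, extra_feats)
  binder <- !all_records$is_non_binder
  all_records$ddg[binder] <- ddg_of(all_records[binder, , drop = FALSE])

  list(records = all_records, features = features_all,
       truth = list(features = truth_features, coefs = coefs,
                    interaction = interaction, intercept = intercept,
                    sigma = sigma, seed = seed,
                    ddg_true = c(ddg_true, rep(NA_real_, nrow(planted) + nrow(nb)))))
}

#' Default toy-complex panel
#'
#' Five small antibody-antigen complexes with varied sequences and
#' interface separations, used by the simulation entry points and tests.
#'
#' @param seed Integer seed.
#' @return Named list of complexes.
#' @export
toy_complex_panel <- function(seed = 1) {
  seqs <- list(
    c(H = "AKYWSDERT", L = "GSTNQHKLM", A = "TNLERYQWF"),
    c(H = "FKDWYSTEQ", A = "RNAYEQTLS"),
    c(H = "MKWYEDSTA", A = "QNLFRYSTE"),
    c(H = "AQYWKDSRE", A = "TNIGRYEWL"),
    c(H = "CKYWSDETN", A = "SNLERYQAM")
  )
  out <- purrr::imap(seqs, function(s, i) {
    ab <- setdiff(names(s), "A")
    make_toy_complex(s, paste(ab, collapse = ","), "A",
                     approach = 3.5 + 0.5 * (i %% 3), seed = seed + i)
  })
  names(out) <- paste0("toy", seq_along(out))
  out
}
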