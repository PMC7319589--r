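# Feature assembly: one named, ordered feature vector per
# (complex, multi-mutation) pair. The name order is the versioned schema the
# trained model embeds (as a hash) and refuses to violate.

#' Pipeline configuration
#'
#' All tunable parameters of the feature and model pipeline in one list:
#' signature bin geometry, interface cutoff, SASA sampling, contact
#' thresholds, the reverse-augmentation and additivity thresholds, and the
#' ensemble hyperparameters.
#'
#' @param interface_cutoff Heavy-atom interface cutoff, Angstrom.
#' @param signature A [signature_params()].
#' @param sasa_probe Probe radius, Angstrom.
#' @param sasa_points Sphere sample points per atom used for features.
#' @param reverse_threshold Reverse-augmentation |ddG| bound, kcal/mol.
#' @param additivity_tol Additive-vs-synergistic tolerance, kcal/mol.
#' @param epsilon Greedy-selection improvement threshold (CV Pearson units).
#' @param num_trees Trees in the ensemble.
#' @param contacts Contact-rule thresholds ([contact_config()]).
#' @return A named list of class `abddg_config`.
#' @export
default_config <- function(interface_cutoff = 5, signature = signature_params(),
                           sasa_probe = 1.4, sasa_points = 240,
                           reverse_threshold = 2, additivity_tol = 1,
                           epsilon = 1e-3, num_trees = 300,
                           contacts = contact_config()) {
  structure(list(interface_cutoff = interface_cutoff, signature = signature,
                 sasa_probe = sasa_probe, sasa_points = sasa_points,
                 reverse_threshold = reverse_threshold,
                 additivity_tol = additivity_tol, epsilon = epsilon,
                 num_trees = num_trees, contacts = contacts),
            class = "abddg_config")
}

FEATURE_FAMILIES <- c("signature", "pharmacophore", "contacts", "sasa",
                      "distances", "evolutionary")

#' Feature schema
#'
#' The fixed, versioned order of feature names for a configuration, with
#' the family tag of each feature.
#'
#' @param config A [default_config()].
#' @return Tibble with `name` and `family`.
#' @export
feature_schema <- function(config = default_config()) {
  pairs <- unordered_class_pairs()
  sig <- sprintf("sig.%s:%s.%g",
                 rep(pairs$a, each = length(config$signature$edges)),
                 rep(pairs$b, each = length(config$signature$edges)),
                 rep(config$signature$edges, nrow(pairs)))
  ct <- as.vector(outer(CONTACT_TYPES, c("all", "interfacial", "sites"),
                        function(a, b) paste0("ct.", a, ".", b)))
  names_ <- c(
    sig,
    paste0("pc.", PHARM_CLASSES),
    ct,
    c("sasa.site", "sasa.total", "sasa.buried"),
    c("dist.mut.min", "dist.mut.mean", "dist.mut.max",
      "dist.partner.min", "dist.partner.mean", "n_sites"),
    c("pam30.sum", "pam30.min", "pssm.wt.sum", "pssm.wt.min",
      "pssm.mt.sum", "pssm.mt.min", "pssm.delta.sum", "pssm.delta.min",
      "pssm.missing")
  )
  family <- c(rep("signature", length(sig)),
              rep("pharmacophore", length(PHARM_CLASSES)),
              rep("contacts", length(ct)),
              rep("sasa", 3), rep("distances", 6),
              rep("evolutionary", 9))
  tibble::tibble(name = names_, family = family)
}

# Wild-type quantities shared by every mutation of the same complex.
precompute_wt <- function(complex, config = default_config(),
                          table = pharmacophore_table()) {
  side <- chain_side(complex)
  s <- sasa(complex, config$sasa_probe, config$sasa_points)
  ab <- sasa(complex[side == "antibody", , drop = FALSE], config$sasa_probe, config$sasa_points)
  ag <- sasa(complex[side == "antigen", , drop = FALSE], config$sasa_probe, config$sasa_points)
  list(contacts = detect_contacts(complex, table), sasa = s,
       sasa_total = sasa_total(s),
       sasa_buried = sasa_total(ab) + sasa_total(ag) - sasa_total(s))
}

#' Compute the feature vector of one multi-mutation
#'
#' Builds the mutant via [build_mutant()], then assembles: the cutoff
#' scanning matrix signature over the union environment of the mutated
#' sites (wild-type structure), pharmacophore changes summed over sites,
#' per-type contact deltas in three scopes, SASA deltas, inter-mutation and
#' mutation-to-partner distances, and evolutionary scores (PAM30 and
#' optional PSSM) aggregated by sum and min over sites.
#'
#' @param complex Wild-type [as_complex()] object.
#' @param specs One multi-mutation spec tibble ([parse_mutation_list()]).
#' @param config A [default_config()].
#' @param pssm Optional named list of `pssm_profile`s by chain ID.
#' @param wt_pre Precomputed wild-type quantities (internal cache; computed
#'   when `NULL`).
#' @param identity Test hook: skip mutation and compare the wild type
#'   against itself; all delta-family features are zero.
#' @return A one-row tibble in [feature_schema()] order.
#' @export
featurize <- function(complex, specs, config = default_config(), pssm = NULL,
                      wt_pre = NULL, identity = FALSE) {
  table <- pharmacophore_table()
  if (is.null(wt_pre)) wt_pre <- precompute_wt(complex, config, table)
  sites <- res_key(specs$chain, specs$resno, specs$icode)
  mutant <- if (identity) complex else build_mutant(complex, specs)

  sig <- signature_vector(csm_signature(complex, sites, config$signature, table))

  if (identity) {
    pc <- stats::setNames(rep(0L, length(PHARM_CLASSES)), paste0("pc.", PHARM_CLASSES))
  } else {
    pc <- Reduce(`+`, purrr::map2(specs$wt, specs$mt, pharmacophore_change, table = table))
  }

  sm <- summarize_contacts(detect_contacts(mutant, table), sites)
  sw <- summarize_contacts(wt_pre$contacts, sites)
  ct <- stats::setNames(
    c(sm$all - sw$all, sm$interfacial - sw$interfacial, sm$sites - sw$sites),
    c(paste0("ct.", sw$type, ".all"), paste0("ct.", sw$type, ".interfacial"),
      paste0("ct.", sw$type, ".sites"))
  )

  side <- chain_side(mutant)
  smt <- sasa(mutant, config$sasa_probe, config$sasa_points)
  smt_ab <- sasa(mutant[side == "antibody", , drop = FALSE], config$sasa_probe, config$sasa_points)
  smt_ag <- sasa(mutant[side == "antigen", , drop = FALSE], config$sasa_probe, config$sasa_points)
  sas <- c(
    sasa.site = sum(smt$area[smt$key %in% sites]) -
      sum(wt_pre$sasa$area[wt_pre$sasa$key %in% sites]),
    sasa.total = sasa_total(smt) - wt_pre$sasa_total,
    sasa.buried = (sasa_total(smt_ab) + sasa_total(smt_ag) - sasa_total(smt)) -
      wt_pre$sasa_buried
  )

  if (length(sites) >= 2) {
    pd <- utils::combn(sites, 2)
    dm <- vapply(seq_len(ncol(pd)), function(k)
      min_heavy_distance(complex, pd[1, k], pd[2, k]), 0)
    dmut <- c(min(dm), mean(dm), max(dm))
  } else dmut <- c(0, 0, 0)  # single-site sentinel
  dpart <- vapply(sites, function(k) dist_to_partner(complex, k), 0)
  dst <- c(dist.mut.min = dmut[1], dist.mut.mean = dmut[2], dist.mut.max = dmut[3],
           dist.partner.min = min(dpart), dist.partner.mean = mean(dpart),
           n_sites = length(sites))

  if (identity) {
    pam <- c(pam30.sum = 0, pam30.min = 0)
    ps <- tibble::tibble(wt_score = 0, mt_score = 0, delta = 0, missing = 0)
  } else {
    pam_site <- pam30_score(specs$wt, specs$mt)
    pam <- c(pam30.sum = sum(pam_site), pam30.min = min(pam_site))
    ps <- purrr::map_dfr(seq_len(nrow(specs)), function(i)
      pssm_features(pssm[[specs$chain[i]]], specs[i, ], complex))
  }
  evo <- c(pam,
           pssm.wt.sum = sum(ps$wt_score), pssm.wt.min = min(ps$wt_score),
           pssm.mt.sum = sum(ps$mt_score), pssm.mt.min = min(ps$mt_score),
           pssm.delta.sum = sum(ps$delta), pssm.delta.min = min(ps$delta),
           pssm.missing = max(ps$missing))

  out <- tibble::as_tibble(as.list(c(sig, pc, ct, sas, dst, evo)))
  schema <- feature_schema(config)
  stopifnot(identical(names(out), schema$name))
  out
}

#' Featurize a record table
#'
#' Computes the feature matrix for affinity records against their complexes,
#' reusing wild-type computations per complex. Reverse records are
#' featurized from the modelled forward-mutant structure as the new
#' wild-type context (never by negating forward features).
#'
#' @param records Affinity-record tibble (`complex_id`, `mutations`,
#'   `is_reverse`).
#' @param complexes Named list of wild-type complexes by `complex_id`.
#' @param config A [default_config()].
#' @param pssms Optional nested list: `pssms[[complex_id]][[chain]]`.
#' @return Tibble of features, rows aligned with `records`.
#' @export
featurize_dataset <- function(records, complexes, config = default_config(),
                              pssms = NULL) {
  caches <- new.env(parent = emptyenv())
  table <- pharmacophore_table()
  get_cache <- function(id, cx) {
    if (is.null(caches[[id]])) caches[[id]] <- precompute_wt(cx, config, table)
    caches[[id]]
  }
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    cx <- complexes[[r$complex_id]]
    if (is.null(cx)) stop("no structure for complex ", r$complex_id)
    specs <- parse_mutation_list(r$mutations)
    pssm <- if (!is.null(pssms)) pssms[[r$complex_id]] else NULL
    if (isTRUE(r$is_reverse)) {
      # swap letters back to recover the forward spec, mutate, re-swap
      fwd <- specs; fwd$wt <- specs$mt; fwd$mt <- specs$wt
      ctx <- build_mutant(cx, fwd)
      featurize(ctx, specs, config, pssm = pssm)
    } else {
      featurize(cx, specs, config, pssm = pssm, wt_pre = get_cache(r$complex_id, cx))
    }
  })
}

#' Median-impute missing evolutionary features
#'
#' PSSM features of records without a profile are imputed with the
#' dataset-median of each column; the `pssm.missing` indicator column is
#' left untouched, and non-evolutionary columns are never modified.
#'
#' @param features Feature tibble.
#' @param medians Optional named medians (from a training set) to reuse.
#' @return List with `features` (imputed) and `medians`.
#' @export
impute_features <- function(features, medians = NULL) {
  cols <- setdiff(grep("^pssm\\.", names(features), value = TRUE), "pssm.missing")
  if (is.null(medians)) {
    medians <- vapply(features[cols], function(x) {
      m <- stats::median(x, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, 0)
  }
  for (cl in cols) {
    x <- features[[cl]]
    x[is.na(x)] <- medians[[cl]]
    features[[cl]] <- x
  }
  list(features = features, medians = medians)
}
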