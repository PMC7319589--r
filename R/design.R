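# Design mode: enumerate all double- and triple-point mutations of interface
# residues on one side of the complex and rank them by predicted ddG.

#' Enumerate candidate interface multi-mutations
#'
#' All `C(n_sites, order)` site combinations times `19^order` substitutions
#' of the interface residues on one side. Proline and glycine substitutions
#' are included (flagged downstream for backbone-strain caveats).
#'
#' @param complex An [as_complex()] object.
#' @param side `"antibody"` or `"antigen"`.
#' @param order 2 (doubles) or 3 (triples).
#' @param interface_cutoff Heavy-atom interface cutoff, Angstrom.
#' @return Tibble of candidates: `set`, `mutation` (string dialect), plus
#'   per-site columns inside the spec rows (`chain`, `wt`, `resno`,
#'   `icode`, `mt`). Empty when `C(n_sites, order) = 0`.
#' @export
enumerate_designs <- function(complex, side = c("antibody", "antigen"),
                              order = 2, interface_cutoff = 5) {
  side <- match.arg(side)
  stopifnot(order %in% 2:3)
  ir <- interface_residues(complex, interface_cutoff)
  ir <- ir[ir$side == side, , drop = FALSE]
  if (nrow(ir) == 0) stop("no interface residues on the ", side, " side")
  if (nrow(ir) < order)
    return(tibble::tibble(set = integer(), mutation = character()))
  combos <- utils::combn(seq_len(nrow(ir)), order)
  res <- purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
    rows <- ir[combos[, ci], , drop = FALSE]
    wt <- aa_one(rows$resname)
    prefix <- paste0(rows$chain, ".", wt, rows$resno, rows$icode)
    subs <- lapply(wt, function(w) setdiff(names(AA3), w))  # 19 each
    grid <- as.matrix(do.call(expand.grid, c(subs, stringsAsFactors = FALSE)))
    tibble::tibble(mutation = apply(grid, 1, function(g)
      paste(paste0(prefix, g), collapse = ";")))
  })
  tibble::tibble(set = seq_len(nrow(res)), mutation = res$mutation)
}

#' Rank design candidates by predicted ddG
#'
#' Scores candidates in batches (bounded memory) and returns the top
#' predicted affinity-increasing and affinity-decreasing lists.
#'
#' @param model A trained `abddg_model`.
#' @param complex The wild-type complex.
#' @param candidates Tibble from [enumerate_designs()] (columns `set`,
#'   `mutation`).
#' @param top_n Length bound of each list (default 100).
#' @param config A [default_config()].
#' @param batch_size Candidates scored per batch.
#' @param verbose Print progress per batch.
#' @return List with tibbles `increasing` (sorted by `ddg_pred`
#'   descending) and `decreasing` (ascending); columns `mutation`,
#'   `ddg_pred`, `dist_interface_min`, `has_gly_pro`, `rank`.
#' @export
rank_designs <- function(model, complex, candidates, top_n = 100,
                         config = default_config(), batch_size = 64,
                         verbose = FALSE) {
  wt_pre <- precompute_wt(complex, config)
  scored <- tibble::tibble()
  batches <- split(seq_len(nrow(candidates)),
                   ceiling(seq_len(nrow(candidates)) / batch_size))
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    rows <- purrr::map_dfr(idx, function(i) {
      specs <- parse_mutation_list(candidates$mutation[i])
      feats <- featurize(complex, specs, config, wt_pre = wt_pre)
      sites <- res_key(specs$chain, specs$resno, specs$icode)
      tibble::tibble(
        mutation = candidates$mutation[i],
        ddg_pred = predict(model, feats),
        dist_interface_min = min(vapply(sites, function(k)
          dist_to_partner(complex, k), 0)),
        has_gly_pro = any(specs$mt %in% c("G", "P"))
      )
    })
    scored <- dplyr::bind_rows(scored, rows)
    # keep only what can still make either top list (bounded buffer)
    if (nrow(scored) > 2 * top_n) {
      ord <- order(scored$ddg_pred)
      scored <- scored[unique(c(utils::head(ord, top_n), utils::tail(ord, top_n))), ]
    }
    if (verbose) message("scored batch ", b, "/", length(batches))
  }
  inc <- dplyr::arrange(scored, dplyr::desc(.data$ddg_pred))[seq_len(min(top_n, nrow(scored))), ]
  dec <- dplyr::arrange(scored, .data$ddg_pred)[seq_len(min(top_n, nrow(scored))), ]
  inc$rank <- seq_len(nrow(inc)); dec$rank <- seq_len(nrow(dec))
  list(increasing = inc, decreasing = dec)
}
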