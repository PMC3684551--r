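#' Pairwise pipeline: mask, anchor, chain, extract, classify, summarize
#'
#' @param ref,query [chromosome_seq()] objects.
#' @param annotations optional reference annotations.
#' @param mask optional telomere [interval_mask()] applied to both sequences
#'   before any indexing (lengths are preserved).
#' @param hash_cfg,chain_cfg,class_cfg configurations.
#' @param out_dir optional directory; when given, the conservation map and
#'   event report are written there as TSV.
#' @return list with `common`, `stats`, `segments`, `events`, `summary`.
#' @export
run_pairwise <- function(ref, query, annotations = NULL, mask = NULL,
                         hash_cfg = hash_config(), chain_cfg = chain_config(),
                         class_cfg = classifier_config(), out_dir = NULL) {
  if (!is.null(mask)) {
    clamp <- function(ch) {
      iv <- mask$intervals
      iv$end <- pmin(iv$end, ch$length)
      iv <- iv[iv$start < iv$end, , drop = FALSE]
      apply_mask(ch, interval_mask(iv, mask$chrom_id))
    }
    ref <- clamp(ref)
    query <- clamp(query)
  }
  ap <- anchor_pair(ref, query, hash_cfg, chain_cfg)
  events <- extract_gaps(ap$segments, ref, query, class_cfg)
  events <- classify_events(events, annotations, class_cfg)
  summ <- summarize_events(events, annotations, mask)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- paste0(query$strain_id, "_vs_", ref$strain_id)
    write_conservation_map(ap$segments,
                           file.path(out_dir, paste0(tag, "_segments.tsv")))
    write_events(events, file.path(out_dir, paste0(tag, "_events.tsv")))
  }
  list(common = ap$common, stats = lgram_statistics(ap$common),
       segments = ap$segments, events = events, summary = summ)
}

#' Multi-strain pipeline: profiles, Hamming distances, mobilome tree
#'
#' Anchors every strain against the reference, intersects the conserved
#' segments into the shared slot structure, builds binary presence/absence
#' profiles at threshold `d`, and clusters strains by UPGMA on Hamming
#' distances. A second threshold (e.g. 300 b, solo-LTR scale) can be given in
#' `d2` to obtain a second profile set from the same anchoring.
#'
#' @param ref reference [chromosome_seq()].
#' @param strains named list of strain [chromosome_seq()] objects (at least
#'   two).
#' @param mask optional telomere [interval_mask()].
#' @param d size threshold in bases (default 4000, transposon scale).
#' @param d2 optional second threshold (e.g. 300).
#' @param hash_cfg,chain_cfg configurations.
#' @param out_dir optional directory for CSV/TSV/newick outputs.
#' @return list with `maps`, `slots`, `profiles`, `profiles_d2` (when
#'   requested), `D`, `tree`, `scores`.
#' @export
run_multistrain <- function(ref, strains, mask = NULL, d = 4000, d2 = NULL,
                            hash_cfg = hash_config(),
                            chain_cfg = chain_config(), out_dir = NULL) {
  if (length(strains) < 2L) stop("multi-strain analysis needs at least 2 strains")
  if (is.null(names(strains)))
    names(strains) <- vapply(strains, `[[`, character(1), "strain_id")
  if (!is.null(mask)) {
    clamp <- function(ch) {
      iv <- mask$intervals
      iv$end <- pmin(iv$end, ch$length)
      iv <- iv[iv$start < iv$end, , drop = FALSE]
      apply_mask(ch, interval_mask(iv, mask$chrom_id))
    }
    ref <- clamp(ref)
    strains <- lapply(strains, clamp)
  }
  idx <- build_index(ref, hash_cfg)
  maps <- lapply(strains, function(s)
    chain_segments(find_common_lgrams(idx, s), chain_cfg))
  slots <- intersect_conserved(maps)
  profiles <- binary_profiles(slots, maps, d = d)
  D <- hamming_matrix(profiles)
  tree <- upgma_tree(D)
  scores <- conservation_scores(profiles)
  out <- list(maps = maps, slots = slots, profiles = profiles, D = D,
              tree = tree, scores = scores)
  if (!is.null(d2)) out$profiles_d2 <- binary_profiles(slots, maps, d = d2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(profiles, file.path(out_dir, "profiles.csv"))
    write.table(D, file.path(out_dir, "hamming.tsv"), sep = "\t", quote = FALSE)
    write_newick(tree, file.path(out_dir, "mobilome_tree.nwk"))
    write.table(scores, file.path(out_dir, "conservation_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Match detected events to a planted truth log
#'
#' For every planted element of length at least `d` the detector is credited
#' a true positive when some significant event of the same strain overlaps it
#' by at least one base — deletions are matched in reference coordinates
#' (their event side is the reference gap), insertions in strain coordinates
#' (the strain-side gap). Detected transposon-scale events that overlap no
#' planted element count as false positives.
#'
#' @param truth the truth log of [simulate_strain_set()].
#' @param events_by_strain named list of classified event data.frames, one
#'   per strain (as produced by [run_pairwise()]).
#' @param d minimum element size evaluated (default 4000).
#' @return list with `TP`, `FN`, `FP`, `Sn` (proportion) and the per-element
#'   match table `detail`.
#' @export
evaluate_planted <- function(truth, events_by_strain, d = 4000) {
  plants <- truth$plants
  plants <- plants[plants$length >= d, , drop = FALSE]
  hit <- logical(nrow(plants))
  for (k in seq_len(nrow(plants))) {
    ev <- events_by_strain[[plants$strain_id[k]]]
    if (is.null(ev) || nrow(ev) == 0L) next
    big <- pmax(ev$gA, ev$gB) >= d
    if (plants$kind[k] == "deletion") {
      hit[k] <- any(big & ev$gA >= d &
                    pmin(ev$ref_end, plants$ref_end[k]) >
                    pmax(ev$ref_start, plants$ref_start[k]))
    } else {
      hit[k] <- any(big & ev$gB >= d &
                    pmin(ev$query_end, plants$strain_end[k]) >
                    pmax(ev$query_start, plants$strain_start[k]))
    }
  }
  fp <- 0
  for (sid in names(events_by_strain)) {
    ev <- events_by_strain[[sid]]
    if (is.null(ev) || nrow(ev) == 0L) next
    ev <- ev[pmax(ev$gA, ev$gB) >= d, , drop = FALSE]
    pl <- truth$plants[truth$plants$strain_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      matched <- any(
        (pl$kind == "deletion" &
           pmin(ev$ref_end[k], pl$ref_end) > pmax(ev$ref_start[k], pl$ref_start)) |
        (pl$kind == "insertion" &
           pmin(ev$query_end[k], pl$strain_end) >
             pmax(ev$query_start[k], pl$strain_start)))
      if (!matched) fp <- fp + 1
    }
  }
  tp <- sum(hit)
  fn <- sum(!hit)
  list(TP = tp, FN = fn, FP = fp,
       Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       detail = cbind(plants, detected = hit))
}

#' Run configuration
#'
#' Aggregates every tunable of the pipeline in one serializable object:
#' gram length and hash width, the chaining gaps, the classifier thresholds,
#' the profile size thresholds and the seed. Round-trips losslessly through
#' JSON via [write_run_config()] / [read_run_config()].
#'
#' @param L,w gram length and hash width (bits).
#' @param delta1,delta2 chaining gaps in bases.
#' @param min_event,ty_min,ltr_max,prox classifier thresholds in bases.
#' @param unresolved_frac,cons_len_tol classifier proportions.
#' @param d,d2 profile size thresholds in bases (`d2` optional).
#' @param seed integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(L = 32L, w = 32L, delta1 = 200L, delta2 = 50L,
                       min_event = 200L, ty_min = 4000L, ltr_max = 500L,
                       prox = 200L, unresolved_frac = 0.5, cons_len_tol = 0.2,
                       d = 4000L, d2 = NULL, seed = 1L) {
  cfg <- list(L = as.integer(L), w = as.integer(w),
              delta1 = as.integer(delta1), delta2 = as.integer(delta2),
              min_event = as.integer(min_event), ty_min = as.integer(ty_min),
              ltr_max = as.integer(ltr_max), prox = as.integer(prox),
              unresolved_frac = unresolved_frac, cons_len_tol = cons_len_tol,
              d = as.integer(d), d2 = if (!is.null(d2)) as.integer(d2),
              seed = as.integer(seed))
  # constructors validate the grouped parameters
  hash_config(cfg$L, cfg$w, cfg$seed)
  chain_config(cfg$delta1, cfg$delta2)
  classifier_config(cfg$min_event, cfg$ty_min, cfg$ltr_max, cfg$prox,
                    cfg$unresolved_frac, cfg$cons_len_tol)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}
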