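#' Classifier configuration
#'
#' Thresholds for the non-conserved-region taxonomy. `min_event` is the
#' significance floor: indels shorter than 200 b are regarded as point-scale
#' noise unrelated to the mobilome. `ty_min` (4000 b) and `ltr_max` (500 b)
#' bound the lengths compatible with a full transposon and a solo-LTR.
#' `prox` is the annotation-proximity radius (200 b). `unresolved_frac` is
#' the minimum N fraction of a strain-side gap for the "unresolved" (u)
#' label, and `cons_len_tol` the relative length tolerance under which a
#' two-sided gap counts as conserved-but-unresolved (pCONSu).
#'
#' @param min_event,ty_min,ltr_max,prox bases.
#' @param unresolved_frac,cons_len_tol proportions in 0..1.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(min_event = 200L, ty_min = 4000L, ltr_max = 500L,
                              prox = 200L, unresolved_frac = 0.5,
                              cons_len_tol = 0.2) {
  if (!(ltr_max > 0 && ltr_max < ty_min)) stop("need 0 < ltr_max < ty_min")
  if (unresolved_frac < 0 || unresolved_frac > 1 ||
      cons_len_tol < 0 || cons_len_tol > 1)
    stop("unresolved_frac and cons_len_tol must be in [0, 1]")
  structure(list(min_event = as.numeric(min_event), ty_min = as.numeric(ty_min),
                 ltr_max = as.numeric(ltr_max), prox = as.numeric(prox),
                 unresolved_frac = unresolved_frac,
                 cons_len_tol = cons_len_tol),
            class = "classifier_config")
}

count_n <- function(seq, start, end) {
  if (end <= start) return(0)
  nchar(gsub("[^N]", "", substr(seq, start + 1, end)))
}

#' Extract non-conserved regions between conserved segments
#'
#' One candidate event per inter-segment gap, plus the leading and trailing
#' gaps; an empty conservation map yields a single event spanning both
#' chromosomes. For each gap the reference-side length `gA`, strain-side
#' length `gB` and the fraction of N in the strain-side gap are computed.
#' Gaps with `max(gA, gB) < min_event` are discarded as insignificant.
#'
#' @param m2 a [chain_segments()] result.
#' @param ref,query the two [chromosome_seq()] objects the map was built from.
#' @param cfg a [classifier_config()].
#' @return data.frame of uncategorized events with columns `ref_start`,
#'   `ref_end`, `query_start`, `query_end`, `gA`, `gB`, `n_frac_query`.
#' @export
extract_gaps <- function(m2, ref, query, cfg = classifier_config()) {
  if (is.character(ref)) ref <- chromosome_seq(ref, "ref", "chr")
  if (is.character(query)) query <- chromosome_seq(query, "query", "chr")
  n <- nrow(m2)
  rs <- c(0, m2$ref_end)
  re <- c(m2$ref_start, ref$length)
  qs <- c(0, m2$query_end)
  qe <- c(m2$query_start, query$length)
  ev <- data.frame(ref_start = rs, ref_end = pmax(rs, re),
                   query_start = qs, query_end = pmax(qs, qe))
  ev$gA <- ev$ref_end - ev$ref_start
  ev$gB <- ev$query_end - ev$query_start
  ev <- ev[pmax(ev$gA, ev$gB) >= cfg$min_event, , drop = FALSE]
  ev$n_frac_query <- vapply(seq_len(nrow(ev)), function(k) {
    if (ev$gB[k] <= 0) return(0)
    count_n(query$seq, ev$query_start[k], ev$query_end[k]) / ev$gB[k]
  }, numeric(1))
  rownames(ev) <- NULL
  ev
}

# boundary-to-boundary distance between half-open intervals; 0 when they touch
# or overlap
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1 - e2, s2 - e1))
}

#' Classify non-conserved regions into the PME taxonomy
#'
#' Categories: `pCONSu` when the reference gap is significant, the strain gap
#' has about the same length (relative tolerance `cons_len_tol`) and is mostly
#' unresolved — the region is presumed conserved but unreadable; `pDEL` when
#' only the reference side is significant (sequence present in the reference,
#' missing in the strain), specializing to `pDEL_Ty` / `pDEL_LTR` when the
#' reference gap overlaps an annotated full-length transposon / solo-LTR;
#' `pINS` when only the strain side is significant (extra sequence in the
#' strain, almost point-wise in the reference), with the `u` suffix (`pINSu`)
#' when the inserted sequence is mostly unresolved; `COMPLEX` when both sides
#' are significant without being pCONSu. The size class compares the event's
#' characteristic length (gA for deletions, gB for insertions, the larger for
#' pCONSu/COMPLEX) with `ty_min` (`Ty_c`) and `ltr_max` (`ltr_c`), anything
#' between is `in_between`. `prox_mobil` flags events whose reference gap lies
#' within `prox` bases of an annotated transposon or solo-LTR.
#'
#' @param events output of [extract_gaps()].
#' @param annotations optional [read_annotations()]-style data.frame on the
#'   reference chromosome.
#' @param cfg a [classifier_config()].
#' @return the events data.frame with columns `category`, `size_class`,
#'   `prox_mobil` and `features` (comma-joined names of overlapping
#'   annotations) appended.
#' @export
classify_events <- function(events, annotations = NULL,
                            cfg = classifier_config()) {
  n <- nrow(events)
  category <- character(n)
  size_class <- character(n)
  prox_mobil <- logical(n)
  features <- character(n)

  mob_classes <- c(ty_full_classes(), ty_ltr_classes())
  ann <- annotations
  has_ann <- !is.null(ann) && nrow(ann) > 0

  for (k in seq_len(n)) {
    gA <- events$gA[k]
    gB <- events$gB[k]
    nf <- events$n_frac_query[k]
    ov_classes <- character(0)
    ov_names <- character(0)
    prox_hit <- FALSE
    if (has_ann) {
      dist <- interval_distance(events$ref_start[k], events$ref_end[k],
                                ann$start, ann$end)
      ov <- dist == 0 & pmin(events$ref_end[k], ann$end) >
                        pmax(events$ref_start[k], ann$start)
      ov_classes <- ann$feature_class[ov]
      ov_names <- ann$name[ov]
      mob <- ann$feature_class %in% mob_classes
      prox_hit <- any(mob & dist <= cfg$prox)
    }

    if (gA >= cfg$min_event &&
        abs(gA - gB) <= cfg$cons_len_tol * max(gA, gB) &&
        nf >= cfg$unresolved_frac) {
      cat_k <- "pCONSu"
      char_len <- max(gA, gB)
    } else if (gA >= cfg$min_event && gB < cfg$min_event) {
      cat_k <- if (any(ov_classes %in% ty_full_classes())) "pDEL_Ty"
               else if (any(ov_classes %in% ty_ltr_classes())) "pDEL_LTR"
               else "pDEL"
      char_len <- gA
    } else if (gB >= cfg$min_event && gA < cfg$min_event) {
      cat_k <- if (nf >= cfg$unresolved_frac) "pINSu" else "pINS"
      char_len <- gB
    } else if (gA >= cfg$min_event && gB >= cfg$min_event) {
      cat_k <- "COMPLEX"
      char_len <- max(gA, gB)
    } else {
      cat_k <- "CONS"
      char_len <- 0
    }

    category[k] <- cat_k
    size_class[k] <- if (cat_k == "CONS") "none"
                     else if (char_len >= cfg$ty_min) "Ty_c"
                     else if (char_len <= cfg$ltr_max) "ltr_c"
                     else "in_between"
    prox_mobil[k] <- prox_hit
    features[k] <- paste(ov_names, collapse = ",")
  }

  events$category <- category
  events$size_class <- size_class
  events$prox_mobil <- prox_mobil
  events$features <- features
  events
}

#' Summarize classified events
#'
#' Counts per category and size class, the prox_mobil fraction, and — when
#' annotations are supplied — deletion counts per annotated feature class.
#' An optional telomere mask adds a telomeric/non-telomeric split.
#'
#' @param events classified events from [classify_events()].
#' @param annotations optional annotation data.frame.
#' @param telomere_mask optional [interval_mask()] on the reference.
#' @return list with data.frames `by_category` and (if annotations given)
#'   `by_feature`, plus the overall `prox_mobil_fraction`.
#' @export
summarize_events <- function(events, annotations = NULL, telomere_mask = NULL) {
  cats <- c("CONS", "pCONSu", "pDEL", "pDEL_Ty", "pDEL_LTR", "pINS", "pINSu",
            "COMPLEX")
  sizes <- c("Ty_c", "ltr_c", "in_between", "none")
  telo <- rep(FALSE, nrow(events))
  if (!is.null(telomere_mask) && nrow(events)) {
    iv <- telomere_mask$intervals
    for (k in seq_len(nrow(events)))
      telo[k] <- any(interval_distance(events$ref_start[k], events$ref_end[k],
                                       iv$start, iv$end) == 0)
  }
  grid <- expand.grid(category = cats, size_class = sizes,
                      telomeric = if (length(telo)) unique(telo) else FALSE,
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(cc, sc, tl)
    sum(events$category == cc & events$size_class == sc & telo == tl),
    grid$category, grid$size_class, grid$telomeric)
  out <- list(by_category = grid,
              prox_mobil_fraction = if (nrow(events))
                mean(events$prox_mobil) else NA_real_)
  if (!is.null(annotations) && nrow(annotations)) {
    dels <- events[startsWith(events$category, "pDEL"), , drop = FALSE]
    cnt <- setNames(numeric(length(unique(annotations$feature_class))),
                    unique(annotations$feature_class))
    if (nrow(dels)) {
      for (k in seq_len(nrow(dels))) {
        ov <- interval_distance(dels$ref_start[k], dels$ref_end[k],
                                annotations$start, annotations$end) == 0 &
              pmin(dels$ref_end[k], annotations$end) >
              pmax(dels$ref_start[k], annotations$start)
        for (cl in unique(annotations$feature_class[ov]))
          cnt[cl] <- cnt[cl] + 1
      }
    }
    out$by_feature <- data.frame(feature_class = names(cnt),
                                 deletions = as.numeric(cnt),
                                 stringsAsFactors = FALSE)
  }
  out
}

#' Write an event report as TSV
#'
#' One row per event, with both 0-based half-open and 1-based inclusive
#' coordinates.
#'
#' @param events classified events.
#' @param path output file.
#' @export
write_events <- function(events, path) {
  out <- events
  out$ref_start1 <- out$ref_start + 1
  out$query_start1 <- out$query_start + 1
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
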