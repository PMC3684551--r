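#' Intersect conserved segments across strains into a slot structure
#'
#' The conserved core of the reference chromosome is the interval
#' intersection, over all strains, of each pairwise conservation map's
#' reference-side intervals: a core base is one that every strain conserves.
#' Slots are the reference intervals between consecutive core intervals
#' (plus a leading and trailing slot when the core does not reach the
#' chromosome ends); they are the shared coordinate system over which
#' per-strain presence/absence profiles are defined.
#'
#' Two subtleties. First, segment boundaries are preserved as cut points: an
#' insertion in some strain interrupts its conserved segments while leaving an
#' almost point-like gap on the reference, so the core is split there and a
#' (possibly zero-width) slot records the junction — its extent lives in
#' strain coordinates, not reference ones. Second, core fragments shorter
#' than L cannot host an anchor and are absorbed into the surrounding slot.
#'
#' @param maps named list of `conservation_map` objects, one per strain, all
#'   against the same reference chromosome.
#' @return object of class `slot_structure` with fields `chrom_id`, `core`
#'   and `slots` (0-based half-open data.frames; slots may be zero-width),
#'   `p` (slot count) and `ref_length`.
#' @export
intersect_conserved <- function(maps) {
  if (length(maps) == 0L) stop("need at least one conservation map")
  ids <- vapply(maps, function(m) attr(m, "ref_id"), character(1))
  if (length(unique(ids)) != 1L)
    stop("conservation maps disagree on the reference id: ",
         paste(unique(ids), collapse = ", "))
  chrom <- attr(maps[[1]], "chrom_id") %||% "chr"
  ref_length <- attr(maps[[1]], "ref_length")
  L <- attr(maps[[1]], "L") %||% 32L

  as_ir <- function(m) {
    if (nrow(m) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(m$ref_start + 1, m$ref_end))
  }
  cov <- Reduce(IRanges::intersect, lapply(maps, as_ir))
  cov_df <- data.frame(start = IRanges::start(cov) - 1, end = IRanges::end(cov))

  # split covered intervals at every strain's segment boundaries
  cuts <- sort(unique(unlist(lapply(maps, function(m)
    c(m$ref_start, m$ref_end)))))
  core_df <- do.call(rbind, lapply(seq_len(nrow(cov_df)), function(k) {
    a <- cov_df$start[k]; b <- cov_df$end[k]
    inner <- cuts[cuts > a & cuts < b]
    bounds <- c(a, inner, b)
    data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  })) %||% data.frame(start = numeric(0), end = numeric(0))
  if (is.null(core_df)) core_df <- data.frame(start = numeric(0), end = numeric(0))
  core_df <- core_df[core_df$end - core_df$start >= L, , drop = FALSE]

  # slots: between consecutive core pieces (zero-width junctions kept),
  # plus non-empty leading/trailing slots
  if (nrow(core_df) == 0L) {
    slot_df <- data.frame(start = 0, end = ref_length)
  } else {
    starts <- core_df$end[-nrow(core_df)]
    ends <- core_df$start[-1]
    slot_df <- data.frame(start = starts, end = ends)
    if (core_df$start[1] > 0)
      slot_df <- rbind(data.frame(start = 0, end = core_df$start[1]), slot_df)
    if (core_df$end[nrow(core_df)] < ref_length)
      slot_df <- rbind(slot_df, data.frame(start = core_df$end[nrow(core_df)],
                                           end = ref_length))
  }
  slot_df <- cbind(slot = seq_len(nrow(slot_df)), slot_df)
  rownames(slot_df) <- rownames(core_df) <- NULL
  structure(list(chrom_id = chrom, core = core_df, slots = slot_df,
                 p = nrow(slot_df), ref_length = ref_length, L = L),
            class = "slot_structure")
}

#' @export
print.slot_structure <- function(x, ...) {
  cat(sprintf("<slot_structure> %s: %d core intervals, p = %d slots over %g bases\n",
              x$chrom_id, nrow(x$core), x$p, x$ref_length))
  invisible(x)
}

# Map a reference coordinate through the strain segment containing it
# (offset from the segment start, clamped to the segment's query interval).
# Returns NA when no segment covers the position.
map_ref_to_query <- function(pos, m) {
  hit <- which(m$ref_start <= pos & pos < m$ref_end)
  if (length(hit) == 0L) return(NA_real_)
  hit <- hit[1]
  min(m$query_start[hit] + (pos - m$ref_start[hit]), m$query_end[hit])
}

#' Strain-side length of each slot
#'
#' For each slot, the span in strain coordinates between the images of the
#' flanking core boundaries: the left boundary is mapped through the strain
#' segment covering the base just left of the slot, the right boundary
#' through the segment covering the base at the slot end; terminal slots are
#' measured to the chromosome ends. When a flank is not covered by any
#' segment of the strain the slot is unmeasurable and falls back to its
#' reference-side length (with a warning).
#'
#' @param slots a [intersect_conserved()] result.
#' @param strain_map the strain's `conservation_map`.
#' @return numeric vector of strain-side slot lengths, with a logical
#'   attribute `measurable`.
#' @export
strain_slot_length <- function(slots, strain_map) {
  m <- as.data.frame(strain_map)
  qlen <- attr(strain_map, "query_length")
  sl <- slots$slots
  n <- nrow(sl)
  len <- numeric(n)
  ok <- rep(TRUE, n)
  for (k in seq_len(n)) {
    s <- sl$start[k]
    e <- sl$end[k]
    # the left core covers up to base s-1; the slot starts right after its image
    ql <- if (s <= 0) 0 else map_ref_to_query(s - 1, m) + 1
    qr <- if (e >= slots$ref_length) qlen else map_ref_to_query(e, m)
    if (is.na(ql) || is.na(qr)) {
      ok[k] <- FALSE
      len[k] <- e - s
    } else {
      len[k] <- max(0, qr - ql)
    }
  }
  if (any(!ok))
    warning(sprintf("%d slot(s) unmeasurable for strain %s; reference length used",
                    sum(!ok), attr(strain_map, "query_id")))
  attr(len, "measurable") <- ok
  len
}

#' Binary mobilome profiles
#'
#' One bit per slot per strain: 1 when the strain-side slot length is at
#' least the size threshold `d`, 0 otherwise. The canonical thresholds are
#' d = 4000 (transposon-compatible, "Ty-c") and d = 300 (down to solo-LTR
#' scale, "solo-ltr-c").
#'
#' @param slots a [intersect_conserved()] result (or list of them, one per
#'   chromosome, in a fixed order — profiles are concatenated).
#' @param maps named list of `conservation_map` per strain (or, for multiple
#'   chromosomes, a list per strain matching `slots`).
#' @param d size threshold in bases.
#' @return binary matrix (strains x slots) of class `mobilome_profiles` with
#'   attribute `d`.
#' @export
binary_profiles <- function(slots, maps, d = 4000) {
  multi <- is.list(slots) && !inherits(slots, "slot_structure")
  strains <- names(maps)
  if (is.null(strains)) stop("maps must be a named list (one entry per strain)")
  row_for <- function(strain) {
    if (multi) {
      unlist(lapply(seq_along(slots), function(c)
        as.integer(strain_slot_length(slots[[c]], maps[[strain]][[c]]) >= d)))
    } else {
      as.integer(strain_slot_length(slots, maps[[strain]]) >= d)
    }
  }
  rows <- lapply(strains, row_for)
  p <- length(rows[[1]])
  prof <- matrix(unlist(rows), nrow = length(strains), ncol = p, byrow = TRUE,
                 dimnames = list(strains,
                                 paste0("slot", seq_len(p), recycle0 = TRUE)))
  structure(prof, d = d, class = c("mobilome_profiles", class(prof)))
}

#' Hamming distance matrix between profiles
#'
#' Raw count of differing bits for every pair of strains (unnormalized; with
#' equal-length vectors normalization is a monotone rescaling that cannot
#' change an average-linkage topology).
#'
#' @param profiles binary matrix (strains x slots) or list of equal-length
#'   binary vectors.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
hamming_matrix <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    lens <- vapply(profiles, length, integer(1))
    if (length(unique(lens)) != 1L) stop("profiles differ in length")
    profiles <- do.call(rbind, profiles)
  }
  if (ncol(profiles) == 0L) {  # no slots at all: every strain is identical
    D <- matrix(0, nrow(profiles), nrow(profiles))
    dimnames(D) <- list(rownames(profiles), rownames(profiles))
    return(D)
  }
  D <- as.matrix(dist(profiles, method = "manhattan"))
  dimnames(D) <- list(rownames(profiles), rownames(profiles))
  D
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted average linkage: the distance between clusters is the
#' size-weighted mean of member distances, and each merge places the new node
#' at half the merge distance, so the result is ultrametric. Ties between
#' equal-distance pairs follow the deterministic order of
#' `stats::hclust(method = "average")`.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal
#'   (labelled rows/columns) and at least two leaves.
#' @return an [ape::as.phylo()] ultrametric tree.
#' @export
upgma_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("UPGMA needs at least 2 leaves")
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0) || any(D < 0))
    stop("D must be symmetric and non-negative with a zero diagonal")
  hc <- hclust(as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Per-slot conservation scores
#'
#' Column sums of the binary profiles: the number of strains (1..K) in which
#' the slot is at least threshold-sized. Slots scoring K in all strains are
#' `almost_conserved` (length-conserved everywhere despite being
#' non-conserved in sequence); the rest are `fully_non_conserved` (at least
#' one strain lacks the element).
#'
#' @param profiles a [binary_profiles()] matrix.
#' @return data.frame with columns `slot`, `score`, `class`.
#' @export
conservation_scores <- function(profiles) {
  K <- nrow(profiles)
  sc <- colSums(profiles)
  data.frame(slot = colnames(profiles), score = as.numeric(sc),
             class = ifelse(sc == K, "almost_conserved", "fully_non_conserved"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sensitivity and specificity from counts
#'
#' `Sn = TP / (TP + FN)` and `Sp = TN / (TN + FP)`, as proportions; `NA` when
#' the denominator is zero.
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return object of class `sens_spec` (a list with the counts and `Sn`,
#'   `Sp`).
#' @export
sens_spec_counts <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be non-negative")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_),
            class = "sens_spec")
}

#' @export
print.sens_spec <- function(x, ...) {
  cat(sprintf("<sens_spec> TP=%g FP=%g TN=%g FN=%g | Sn = %.1f%% Sp = %.1f%%\n",
              x$TP, x$FP, x$TN, x$FN, 100 * x$Sn, 100 * x$Sp))
  invisible(x)
}

#' Sensitivity and specificity of interval predictions
#'
#' A prediction hits a truth element iff their intervals overlap by at least
#' one base. TP counts truth elements hit by some prediction, FN the missed
#' truth elements, FP the predictions hitting nothing, and TN the remaining
#' evaluable units: `universe - TP - FN - FP`.
#'
#' @param predicted,truth data.frames with `start`, `end` columns in the same
#'   coordinate frame (optionally a `strain_id` column, matched when present
#'   in both).
#' @param universe total number of evaluable units (positive integer).
#' @return a [sens_spec_counts()] object.
#' @export
sens_spec <- function(predicted, truth, universe) {
  if (missing(universe) || length(universe) != 1L || universe <= 0)
    stop("universe must be a positive count of evaluable units")
  both_strain <- !is.null(predicted$strain_id) && !is.null(truth$strain_id)
  hit_one <- function(s, e, df, sid) {
    sel <- if (both_strain) df$strain_id == sid else rep(TRUE, nrow(df))
    any(sel & pmin(e, df$end) > pmax(s, df$start))
  }
  tp <- if (nrow(truth)) sum(vapply(seq_len(nrow(truth)), function(k)
    hit_one(truth$start[k], truth$end[k], predicted,
            if (both_strain) truth$strain_id[k] else NA), logical(1))) else 0
  fn <- nrow(truth) - tp
  fp <- if (nrow(predicted)) sum(!vapply(seq_len(nrow(predicted)), function(k)
    hit_one(predicted$start[k], predicted$end[k], truth,
            if (both_strain) predicted$strain_id[k] else NA), logical(1))) else 0
  tn <- universe - tp - fn - fp
  if (tn < 0) stop("universe smaller than the observed units")
  sens_spec_counts(tp, fp, tn, fn)
}

#' Write a tree as newick
#'
#' @param tree an ape `phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
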