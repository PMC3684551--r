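#' Build an L-gram index of a reference chromosome
#'
#' Hashes every valid (N-free) window of the reference with the cyclic
#' rolling hash and stores the positions in a hash table (load factor 0.75).
#' Only maximal ACGT runs of length at least L are scanned, so windows
#' overlapping unresolved bases are absent by construction.
#'
#' @param ref a [chromosome_seq()] or base string.
#' @param cfg a [hash_config()].
#' @return an opaque index of class `lgram_index`.
#' @export
build_index <- function(ref, cfg = hash_config()) {
  if (is.character(ref)) ref <- chromosome_seq(ref, "ref", "chr")
  if (cfg$L > ref$length)
    warning("L exceeds the reference length; index is empty")
  ptr <- cpp_build_index(ref$seq, cfg$L, cfg$codes, cfg$w)
  structure(list(ptr = ptr, ref = ref, cfg = cfg), class = "lgram_index")
}

#' @export
print.lgram_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("<lgram_index> %s | %s : %d bases, %g indexed windows (L = %d)\n",
              x$ref$strain_id, x$ref$chrom_id, x$ref$length,
              info$n_positions, x$cfg$L))
  invisible(x)
}

#' Occurrence list of one exact L-gram in an index
#'
#' String-verified occurrences (ascending, 0-based); hash collisions can never
#' surface here.
#'
#' @param index an [build_index()] result.
#' @param gram a base string of length L.
#' @return integer vector of 0-based start positions.
#' @export
index_occurrences <- function(index, gram) cpp_index_lookup(index$ptr, gram)

#' Number of indexed windows
#'
#' Count of valid (N-free) L-gram positions stored in the index.
#'
#' @param index an [build_index()] result.
#' @return a count.
#' @export
index_size <- function(index) cpp_index_info(index$ptr)$n_positions

#' Find the common L-grams of a query against an indexed reference
#'
#' Phase 1 of the pairwise comparison. Every valid query window is hashed with
#' the rolling scheme, looked up in the reference index, and each candidate
#' occurrence is confirmed by direct base-string comparison. The result maps
#' each common query position j to its ascending occurrence list in the
#' reference, together with L-gram statistics: `total` windows (m - L + 1),
#' `valid` (N-free), `common` (valid with at least one occurrence) and `multi`
#' (common with two or more occurrences).
#'
#' @param index reference index from [build_index()].
#' @param query a [chromosome_seq()] or base string.
#' @return object of class `common_map` with fields `j` (0-based query
#'   positions), `occs` (list of 0-based reference occurrence vectors),
#'   `stats`, plus sequence metadata.
#' @export
find_common_lgrams <- function(index, query) {
  if (is.character(query)) query <- chromosome_seq(query, "query", "chr")
  res <- cpp_find_common(index$ptr, query$seq)
  mr <- gregexpr("N+", query$seq)[[1]]
  n_runs <- if (mr[1] == -1) data.frame(start = numeric(0), end = numeric(0))
            else data.frame(start = as.numeric(mr) - 1,
                            end = as.numeric(mr) - 1 +
                                  attr(mr, "match.length"))
  structure(list(L = index$cfg$L,
                 ref_id = index$ref$strain_id, query_id = query$strain_id,
                 chrom_id = query$chrom_id,
                 ref_length = index$ref$length, query_length = query$length,
                 j = res$j, occs = res$occs, stats = res$stats,
                 query_n_runs = n_runs),
            class = "common_map")
}

#' @export
print.common_map <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<common_map> %s vs %s (%s): L = %d\n",
                     "  windows %g | valid %g (%.1f%%) | common %g (%.1f%%)",
                     " | multi %g (%.1f%%)\n"),
              x$query_id, x$ref_id, x$chrom_id, x$L,
              s$total, s$valid, 100 * s$valid / max(1, s$total),
              s$common, 100 * s$common / max(1, s$total),
              s$multi, 100 * s$multi / max(1, s$total)))
  invisible(x)
}

#' L-gram statistics of a common map
#'
#' @param M a [find_common_lgrams()] result.
#' @return list with counts `total`, `valid`, `common`, `multi` and the
#'   corresponding fractions over `total`.
#' @export
lgram_statistics <- function(M) {
  s <- M$stats
  tot <- max(1, s$total)
  list(total = s$total, valid = s$valid, common = s$common, multi = s$multi,
       frac_valid = s$valid / tot, frac_common = s$common / tot,
       frac_multi = s$multi / tot)
}

#' Chaining configuration
#'
#' `delta1` bounds the query-side gap between consecutive anchors of one
#' segment (d2 <= delta1); `delta2` bounds the indel tolerance |d1 - d2|
#' inside a segment, where d1 and d2 are the base gaps between consecutive
#' anchors on the reference and query sides. Hence any single bridgeable
#' reference gap satisfies d1 <= delta1 + delta2. Defaults keep intra-segment
#' gaps below the 200 b event-significance scale and the bridgeable indel
#' well below the ~300 b solo-LTR scale, so solo-LTR-sized indels always open
#' a new segment.
#'
#' @param delta1,delta2 non-negative gap thresholds in bases.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(delta1 = 200L, delta2 = 50L) {
  if (delta1 < 0 || delta2 < 0) stop("delta1 and delta2 must be non-negative")
  structure(list(delta1 = as.integer(delta1), delta2 = as.integer(delta2)),
            class = "chain_config")
}

#' Chain common L-grams into conserved segment pairs
#'
#' Phase 2: a greedy left-to-right scan over the common map. (1) The next
#' segment starts at the leftmost unconsumed common L-gram; its image is the
#' nearest admissible reference occurrence (ties to the smaller coordinate),
#' where admissible means at or beyond the end of the last emitted reference
#' interval, which keeps segments colinear and disjoint on both sides.
#' (2) The segment is extended anchor by anchor while the query gap satisfies
#' d2 <= delta1, the new occurrence lies strictly right of the current image,
#' and |d1 - d2| <= delta2; among admissible occurrences the one minimizing
#' |d1 - d2| is chosen (ties to the smaller coordinate). Anchors with no
#' admissible occurrence are skipped; extension stops at the first anchor
#' beyond delta1. (3) The closed pair `[first, last + L)` on both sides is
#' emitted.
#'
#' @param M a `common_map`.
#' @param cfg a [chain_config()].
#' @return a `conservation_map`: data.frame with columns `ref_start`,
#'   `ref_end`, `query_start`, `query_end`, `anchors` (0-based half-open),
#'   ordered and strictly increasing on both sides, with comparison metadata
#'   in attributes.
#' @export
chain_segments <- function(M, cfg = chain_config()) {
  stopifnot(inherits(M, "common_map"))
  seg <- cpp_chain(M$j, M$occs, M$L, cfg$delta1, cfg$delta2)
  df <- as.data.frame(seg)
  attr(df, "ref_id") <- M$ref_id
  attr(df, "query_id") <- M$query_id
  attr(df, "chrom_id") <- M$chrom_id
  attr(df, "ref_length") <- M$ref_length
  attr(df, "query_length") <- M$query_length
  attr(df, "L") <- M$L
  attr(df, "delta1") <- cfg$delta1
  attr(df, "delta2") <- cfg$delta2
  class(df) <- c("conservation_map", "data.frame")
  df
}

#' Write a conservation map as TSV
#'
#' Internal 0-based half-open coordinates plus 1-based inclusive companions
#' for human comparison.
#'
#' @param m2 a [chain_segments()] result.
#' @param path output file.
#' @export
write_conservation_map <- function(m2, path) {
  out <- as.data.frame(m2)
  out$ref_start1 <- out$ref_start + 1
  out$ref_end1 <- out$ref_end
  out$query_start1 <- out$query_start + 1
  out$query_end1 <- out$query_end
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convenience pairwise anchoring
#'
#' Runs [build_index()], [find_common_lgrams()] and [chain_segments()] in one
#' call.
#'
#' @param ref,query [chromosome_seq()] objects or base strings.
#' @param hash_cfg,chain_cfg configurations.
#' @return list with `common` (the `common_map`) and `segments` (the
#'   `conservation_map`).
#' @export
anchor_pair <- function(ref, query, hash_cfg = hash_config(),
                        chain_cfg = chain_config()) {
  idx <- build_index(ref, hash_cfg)
  cm <- find_common_lgrams(idx, query)
  list(common = cm, segments = chain_segments(cm, chain_cfg))
}
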