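#' Two-track plot of common L-grams
#'
#' Reference on the top track, strain on the bottom; one line connects the
#' start positions of each common L-gram pair (using the nearest reference
#' occurrence). Conserved colinear regions appear as dense near-vertical
#' bundles; an insertion in the strain opens an empty triangle with no lines,
#' a deletion the mirror image. Annotation rectangles are drawn under the top
#' track and N-run rectangles over the bottom track. Lines are subsampled
#' above `max_lines` — a 2 Mb chromosome drawn anchor-by-anchor is unreadable
#' and structural tests never depend on rendering.
#'
#' @param M a `common_map`.
#' @param events optional classified events (highlighted along the tracks).
#' @param annotations optional reference annotations.
#' @param region optional `c(start, end)` window on the reference (0-based
#'   half-open); default the whole reference.
#' @param out optional PNG path; when `NULL` the current device is used.
#' @param max_lines density cap for anchor lines.
#' @return (invisibly) the structural content: data.frame `lines` with
#'   `ref_pos`, `query_pos`, plus `n_runs` and `annotations` rectangles.
#' @export
plot_anchor_tracks <- function(M, events = NULL, annotations = NULL,
                               region = NULL, out = NULL, max_lines = 2000L) {
  region <- region %||% c(0, M$ref_length)
  near <- vapply(seq_along(M$j), function(k) {
    oc <- M$occs[[k]]
    oc[which.min(abs(M$j[k] - oc))]
  }, numeric(1))
  lines <- data.frame(ref_pos = near, query_pos = M$j)
  lines <- lines[lines$ref_pos >= region[1] & lines$ref_pos < region[2], ,
                 drop = FALSE]
  if (nrow(lines) > max_lines)
    lines <- lines[seq(1, nrow(lines), length.out = max_lines), , drop = FALSE]

  runs <- M$query_n_runs %||%
    data.frame(start = numeric(0), end = numeric(0))
  ann <- if (!is.null(annotations))
    annotations[annotations$end > region[1] & annotations$start < region[2], ,
                drop = FALSE]
  else NULL

  if (!is.null(out)) {
    grDevices::png(out, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(NA, xlim = region, ylim = c(-0.3, 1.3), xlab = "position (b)",
                 ylab = "", yaxt = "n",
                 main = sprintf("%s (top) vs %s (bottom)", M$ref_id, M$query_id))
  graphics::axis(2, at = c(0, 1), labels = c(M$query_id, M$ref_id), las = 1)
  graphics::abline(h = c(0, 1), col = "grey40")
  if (nrow(lines))
    graphics::segments(lines$ref_pos, 1, lines$query_pos, 0,
                       col = grDevices::adjustcolor("forestgreen", 0.3))
  if (!is.null(ann) && nrow(ann))
    graphics::rect(ann$start, 1.05, ann$end, 1.2, col = "tomato", border = NA)
  if (nrow(runs))
    graphics::rect(runs$start, -0.2, runs$end, -0.05, col = "black", border = NA)
  if (!is.null(events) && nrow(events))
    graphics::rect(events$ref_start, 0.45, pmax(events$ref_end,
                   events$ref_start + diff(region) / 400), 0.55,
                   col = grDevices::adjustcolor("purple", 0.5), border = NA)
  invisible(list(lines = lines, n_runs = runs, annotations = ann,
                 region = region))
}
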