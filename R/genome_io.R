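#' Construct a chromosome sequence
#'
#' Canonicalizes the sequence: letters are upper-cased, and any IUPAC
#' ambiguity code other than N (or any other character) is converted to N and
#' counted. N marks unresolved bases, which the anchoring layer skips; in
#' low-coverage assemblies long N runs are common and are treated as
#' first-class signal downstream (putative unresolved conservation).
#'
#' @param seq base string.
#' @param strain_id,chrom_id identifiers.
#' @return an object of class `chromosome_seq` with fields `strain_id`,
#'   `chrom_id`, `seq`, `length` and `n_converted` (count of characters
#'   canonicalized to N).
#' @export
chromosome_seq <- function(seq, strain_id = "strain", chrom_id = "chr") {
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be a single string")
  up <- toupper(seq)
  n_converted <- nchar(gsub("[ACGTN]", "", up))
  if (n_converted > 0) up <- gsub("[^ACGTN]", "N", up)
  structure(list(strain_id = strain_id, chrom_id = chrom_id, seq = up,
                 length = nchar(up), n_converted = n_converted),
            class = "chromosome_seq")
}

#' @export
print.chromosome_seq <- function(x, ...) {
  cat(sprintf("<chromosome_seq> %s | %s : %d bases (%d converted to N)\n",
              x$strain_id, x$chrom_id, x$length, x$n_converted))
  invisible(x)
}

# "strain|chrom" header convention; a bare token is taken as the strain id.
parse_fasta_header <- function(nm) {
  token <- sub("\\s.*$", "", nm)
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L) list(strain = parts[1], chrom = parts[2])
  else list(strain = token, chrom = "chr")
}

#' Read chromosomes from FASTA
#'
#' One `chromosome_seq` per record. Headers of the form `strain|chrom` are
#' split into the two identifiers; otherwise the first whitespace-delimited
#' token is the strain id. Sequences are canonicalized (case folded, ambiguity
#' codes to N) and the number of converted characters per record is reported
#' via `message()` when nonzero.
#'
#' @param path FASTA file.
#' @return list of [chromosome_seq()] objects, named `strain|chrom`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input: ", path)
  out <- lapply(seq_along(set), function(k) {
    ids <- parse_fasta_header(names(set)[k])
    cs <- chromosome_seq(as.character(set[[k]]), ids$strain, ids$chrom)
    if (cs$n_converted > 0)
      message(sprintf("record %s: %d ambiguity characters converted to N",
                      names(set)[k], cs$n_converted))
    cs
  })
  names(out) <- vapply(out, function(c) paste(c$strain_id, c$chrom_id, sep = "|"),
                       character(1))
  out
}

#' Write chromosomes to FASTA
#'
#' Headers follow the writer's `strain|chrom` convention, so
#' `read_fasta(write_fasta(x))` round-trips sequences and identifiers exactly.
#'
#' @param chroms list of [chromosome_seq()] (or a single one).
#' @param path output file.
#' @export
write_fasta <- function(chroms, path) {
  if (inherits(chroms, "chromosome_seq")) chroms <- list(chroms)
  set <- Biostrings::BStringSet(vapply(chroms, `[[`, character(1), "seq"))
  names(set) <- vapply(chroms, function(c)
    paste(c$strain_id, c$chrom_id, sep = "|"), character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Canonical feature-class vocabulary. Full-length transposon families and
# their solo-LTR counterparts get dedicated classes; everything else that the
# class map does not resolve collapses to "other".
feature_classes <- function() {
  c(paste0("Ty", 1:5), paste0("Ty", 1:5, "ltr"),
    "tRNA", "ARS", "MRhotspot", "EvolutiveBreakpoint",
    "ExperimentalBreakpoint", "gammaH2A", "TER", "other")
}

ty_full_classes <- function() paste0("Ty", 1:5)
ty_ltr_classes <- function() paste0("Ty", 1:5, "ltr")

#' Read feature annotations (GFF3 or BED)
#'
#' Coordinates are converted to the internal 0-based half-open convention
#' (GFF3 is 1-based inclusive, BED already 0-based half-open; both arrive
#' 1-based from the importer and are shifted uniformly). The feature class is
#' taken from the GFF3 `type` column (falling back to the `Name` attribute) or
#' the BED name field, then passed through `class_map`; unknown classes map to
#' `"other"`.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"bed"`.
#' @param class_map optional named character vector mapping raw keywords to
#'   canonical classes (see `feature_classes()`); matching is case-sensitive
#'   on the raw keyword.
#' @return data.frame with columns `chrom_id`, `start`, `end` (0-based
#'   half-open), `feature_class`, `name`.
#' @export
read_annotations <- function(path, dialect = c("gff3", "bed"), class_map = NULL) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = dialect)
  if (length(gr) == 0L)
    return(data.frame(chrom_id = character(), start = numeric(),
                      end = numeric(), feature_class = character(),
                      name = character(), stringsAsFactors = FALSE))
  df <- as.data.frame(gr)
  raw <- if (dialect == "gff3") {
    v <- as.character(df$type)
    if (!is.null(df$Name)) {
      nm <- as.character(df$Name)
      v <- ifelse(!is.na(nm) & nm %in% feature_classes(), nm, v)
    }
    v
  } else {
    if (!is.null(df$name)) as.character(df$name) else rep("other", nrow(df))
  }
  if (!is.null(class_map)) {
    hit <- raw %in% names(class_map)
    raw[hit] <- unname(class_map[raw[hit]])
  }
  cls <- ifelse(raw %in% feature_classes(), raw, "other")
  nm <- if (!is.null(df$Name)) as.character(df$Name)
        else if (!is.null(df$name)) as.character(df$name) else raw
  ann <- data.frame(chrom_id = as.character(df$seqnames),
                    start = df$start - 1,
                    end = as.numeric(df$end),
                    feature_class = cls,
                    name = ifelse(is.na(nm), raw, nm),
                    stringsAsFactors = FALSE)
  bad <- which(ann$end <= ann$start)
  if (length(bad))
    stop("annotation records with end <= start after conversion at lines: ",
         paste(bad, collapse = ", "))
  ann
}

#' Interval mask
#'
#' Sorted, non-overlapping half-open intervals on one chromosome; overlapping
#' or touching input intervals are merged. Used mainly to blank out telomeric
#' regions, whose intrinsic instability would otherwise flood the
#' non-conserved output.
#'
#' @param intervals data.frame with 0-based half-open `start`, `end` columns.
#' @param chrom_id chromosome identifier.
#' @return object of class `interval_mask`.
#' @export
interval_mask <- function(intervals, chrom_id = "chr") {
  if (nrow(intervals) == 0L) {
    iv <- data.frame(start = numeric(), end = numeric())
  } else {
    if (any(intervals$end <= intervals$start)) stop("mask intervals need end > start")
    ir <- IRanges::reduce(IRanges::IRanges(intervals$start + 1, intervals$end))
    iv <- data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
  }
  structure(list(chrom_id = chrom_id, intervals = iv), class = "interval_mask")
}

#' Read an interval mask from BED
#'
#' @param path BED file of intervals (e.g. telomeres) on one chromosome.
#' @return an [interval_mask()].
#' @export
read_mask <- function(path) {
  df <- as.data.frame(rtracklayer::import(path, format = "bed"))
  interval_mask(data.frame(start = df$start - 1, end = as.numeric(df$end)),
                chrom_id = if (nrow(df)) as.character(df$seqnames[1]) else "chr")
}

#' Mask intervals of a chromosome with N
#'
#' Masked positions are replaced by N; the length is preserved so coordinates
#' stay comparable across strains. The anchoring layer then skips the masked
#' windows exactly as it skips genuinely unresolved runs.
#'
#' @param chrom a [chromosome_seq()].
#' @param mask an [interval_mask()] (or a data.frame of `start`, `end`).
#' @return a new [chromosome_seq()] of identical length.
#' @export
apply_mask <- function(chrom, mask) {
  iv <- if (inherits(mask, "interval_mask")) mask$intervals else mask
  s <- chrom$seq
  if (nrow(iv)) {
    if (any(iv$start < 0) || any(iv$end > chrom$length))
      stop("mask interval out of chromosome bounds")
    for (k in seq_len(nrow(iv)))
      substr(s, iv$start[k] + 1, iv$end[k]) <- strrep("N", iv$end[k] - iv$start[k])
  }
  out <- chromosome_seq(s, chrom$strain_id, chrom$chrom_id)
  out$n_converted <- chrom$n_converted
  out
}
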