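#' Random reference chromosome
#'
#' Uniform i.i.d. sequence over \{A,C,G,T\}; deterministic for a fixed seed.
#'
#' @param length chromosome length in bases (at least 10 L is sensible for
#'   anchoring with gram length L).
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param strain_id,chrom_id identifiers.
#' @return a [chromosome_seq()].
#' @export
make_reference <- function(length, seed = NULL, strain_id = "ref",
                           chrom_id = "chr1") {
  if (length < 1) stop("length must be positive")
  draw <- function() paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                           collapse = "")
  s <- if (is.null(seed)) draw() else with_seed(seed, draw())
  chromosome_seq(s, strain_id, chrom_id)
}

#' Synthetic mobile-element library
#'
#' A fixed set of canonical element sequences: three full-length
#' transposon-like families of 8000 b (`synTy1`..`synTy3`) and one 300 b
#' solo-LTR-like element (`synLTR`). Insertions of one family draw prefixes of
#' the same canonical sequence, so repeated copies are near-identical — the
#' way real transposon copies are.
#'
#' @param seed integer seed for the (one-off, documented) library draw.
#' @return named list of base strings.
#' @export
element_library <- function(seed = 77L) {
  with_seed(seed, {
    lib <- lapply(c(synTy1 = 8000, synTy2 = 8000, synTy3 = 8000, synLTR = 300),
                  function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = ""))
    lib
  })
}

# footprint of a plant on the reference: deletions occupy their interval,
# insertions a single point
plant_footprint <- function(plants) {
  data.frame(start = plants$position,
             end = plants$position +
               ifelse(plants$kind == "deletion", plants$length, 0))
}

#' Derive a strain from a reference by planting events
#'
#' Applies deletions and insertions left to right with full coordinate
#' bookkeeping, then point mutations, then runs of unresolved bases. SNPs and
#' N-runs are kept at least `collar` bases away from every event boundary so
#' that measured gap lengths stay crisp against the truth log, and outside
#' inserted elements so that copies of one family stay near-identical.
#'
#' @param ref reference [chromosome_seq()].
#' @param plants data.frame with columns `kind` ("insertion"/"deletion"),
#'   `position` (0-based reference coordinate; for deletions the start of the
#'   removed interval), `length`, `element_label` (a name in
#'   [element_library()], or `"random"`).
#' @param snp_rate per-base substitution probability.
#' @param n_runs either `NULL`, a data.frame of strain-frame `start`,`end`
#'   intervals, or a list `list(n =, min_len =, max_len =)` to place runs at
#'   random away from events.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @param strain_id strain identifier.
#' @param collar exclusion radius around event boundaries in bases
#'   (default 32, one gram length).
#' @param library element library (defaults to [element_library()]).
#' @return list with `chrom` (the derived [chromosome_seq()]) and `truth`
#'   (plants with realized `ref_start`,`ref_end`,`strain_start`,`strain_end`,
#'   SNP positions, N-run intervals).
#' @export
derive_strain <- function(ref, plants, snp_rate = 0, n_runs = NULL,
                          seed = NULL, strain_id = "strain", collar = 32L,
                          library = element_library()) {
  run <- function() {
    m <- ref$length
    if (nrow(plants)) {
      plants <- plants[order(plants$position), , drop = FALSE]
      fp <- plant_footprint(plants)
      if (any(fp$end > m) || any(fp$start < 0)) stop("plant outside reference")
      if (nrow(fp) > 1 && any(fp$start[-1] < fp$end[-nrow(fp)]))
        stop("overlapping plants")
    }
    pieces <- character(0)
    truth <- plants[0, , drop = FALSE]
    rs <- re <- ss <- se <- numeric(nrow(plants))
    cur <- 0
    shift <- 0
    ins_intervals <- NULL
    for (k in seq_len(nrow(plants))) {
      p <- plants$position[k]
      l <- plants$length[k]
      pieces <- c(pieces, substr(ref$seq, cur + 1, p))
      if (plants$kind[k] == "insertion") {
        lab <- plants$element_label[k]
        elseq <- if (!is.null(library[[lab]])) {
          if (l > nchar(library[[lab]]))
            stop("requested insertion longer than the canonical element")
          substr(library[[lab]], 1, l)
        } else {
          paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
        }
        pieces <- c(pieces, elseq)
        rs[k] <- p; re[k] <- p
        ss[k] <- p + shift; se[k] <- p + shift + l
        ins_intervals <- rbind(ins_intervals, c(ss[k], se[k]))
        shift <- shift + l
        cur <- p
      } else {
        rs[k] <- p; re[k] <- p + l
        ss[k] <- p + shift; se[k] <- p + shift
        shift <- shift - l
        cur <- p + l
      }
    }
    pieces <- c(pieces, substr(ref$seq, cur + 1, m))
    s <- paste(pieces, collapse = "")
    n <- nchar(s)

    # positions eligible for SNPs / N-runs: outside every event collar and
    # outside inserted elements
    eligible <- rep(TRUE, n)
    block <- function(a, b) {
      a <- max(0, a); b <- min(n, b)
      if (b > a) eligible[(a + 1):b] <<- FALSE
    }
    for (k in seq_len(nrow(plants))) block(ss[k] - collar, se[k] + collar)

    snp_pos <- integer(0)
    if (snp_rate > 0) {
      idx <- which(eligible)
      n_snp <- rbinom(1, length(idx), snp_rate)
      if (n_snp > 0) {
        snp_pos <- sort(sample(idx, n_snp))
        chars <- strsplit(s, "")[[1]]
        for (pp in snp_pos) {
          alt <- setdiff(c("A", "C", "G", "T"), chars[pp])
          chars[pp] <- sample(alt, 1)
        }
        s <- paste(chars, collapse = "")
      }
    }

    run_df <- data.frame(start = numeric(0), end = numeric(0))
    if (!is.null(n_runs)) {
      if (is.data.frame(n_runs)) {
        run_df <- n_runs
      } else {
        for (r in seq_len(n_runs$n)) {
          len <- sample(seq(n_runs$min_len, n_runs$max_len), 1)
          # maximal eligible stretches able to hold the run
          el <- rle(eligible)
          endp <- cumsum(el$lengths)
          startp <- endp - el$lengths
          okr <- which(el$values & el$lengths >= len + 2)
          if (length(okr) == 0L) {
            warning("no room left for an N-run; skipped")
            next
          }
          pick <- okr[sample(length(okr), 1)]
          off <- sample(0:(el$lengths[pick] - len), 1)
          st <- startp[pick] + off
          run_df <- rbind(run_df, data.frame(start = st, end = st + len))
          eligible[(st + 1):(st + len)] <- FALSE
        }
      }
      for (k in seq_len(nrow(run_df)))
        substr(s, run_df$start[k] + 1, run_df$end[k]) <-
          strrep("N", run_df$end[k] - run_df$start[k])
    }

    truth <- plants
    truth$ref_start <- rs; truth$ref_end <- re
    truth$strain_start <- ss; truth$strain_end <- se
    truth$strain_id <- rep(strain_id, nrow(plants))
    list(chrom = chromosome_seq(s, strain_id, ref$chrom_id),
         truth = list(plants = truth,
                      snps = data.frame(strain_id =
                               rep(strain_id, length(snp_pos)),
                               pos = snp_pos - 1),
                      n_runs = if (nrow(run_df))
                        cbind(strain_id = strain_id, run_df)
                      else data.frame(strain_id = character(0),
                                      start = numeric(0), end = numeric(0))))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a reference plus derived strain set with a truth log
#'
#' The default fixture emulates the study conditions the rest of the package
#' is validated on: a 100 kb random reference chromosome; 5 derived strains,
#' each carrying 3 insertions and 3 deletions of transposon-sized elements
#' (5000-8000 b) at well-separated loci; point mutations at rate 0.005 kept
#' one gram length away from event boundaries; and two 1-2 kb runs of
#' unresolved bases per strain placed away from events. Deleted reference
#' intervals are annotated as synthetic transposon copies (classes Ty1-Ty3),
#' and, when `ltr_near_insertions` is `TRUE`, a 300 b synthetic solo-LTR
#' annotation is placed right of each insertion point, emulating the
#' tendency of insertions to land near resident elements.
#'
#' With `clades`, strains in the same clade share one planted-event history
#' (SNPs and N-runs stay strain-specific), which produces an unambiguous
#' expected topology for the mobilome tree.
#'
#' @param seed integer seed; the whole strain set is a deterministic function
#'   of it.
#' @param n_strains number of derived strains.
#' @param ref_length reference length in bases.
#' @param n_insertions,n_deletions planted events per strain (or per clade).
#' @param element_length length range (min, max) of planted elements.
#' @param snp_rate per-base substitution rate.
#' @param n_runs number of N-runs per strain.
#' @param n_run_length length range of the N-runs.
#' @param clades optional list of integer vectors partitioning 1..n_strains.
#' @param ltr_near_insertions annotate a synthetic solo-LTR next to each
#'   insertion point.
#' @param margin telomere-like margin at both chromosome ends kept free of
#'   events.
#' @return list with `reference`, `strains` (named list of
#'   [chromosome_seq()]), `truth` (plants/snps/n_runs/seed/params),
#'   `annotations` (reference features) and `params`.
#' @export
simulate_strain_set <- function(seed = 1L, n_strains = 5L, ref_length = 100000L,
                                n_insertions = 3L, n_deletions = 3L,
                                element_length = c(5000L, 8000L),
                                snp_rate = 0.005, n_runs = 2L,
                                n_run_length = c(1000L, 2000L),
                                clades = NULL, ltr_near_insertions = TRUE,
                                margin = 3000L) {
  lib <- element_library()
  n_ev <- n_insertions + n_deletions
  groups <- clades %||% as.list(seq_len(n_strains))
  if (!setequal(unlist(groups), seq_len(n_strains)))
    stop("clades must partition 1..n_strains")

  with_seed(seed, {
    reference <- make_reference(ref_length, seed = NULL)

    plan_group <- function() {
      span <- ref_length - 2 * margin
      bin <- span / n_ev
      maxlen <- element_length[2]
      if (bin < maxlen + 1000)
        stop("reference too short for this many well-separated events")
      kinds <- sample(c(rep("insertion", n_insertions),
                        rep("deletion", n_deletions)))
      pos <- vapply(seq_len(n_ev), function(k) {
        lo <- margin + (k - 1) * bin
        floor(lo + runif(1, 500, bin - maxlen - 500))
      }, numeric(1))
      len <- sample(seq(element_length[1], element_length[2]), n_ev,
                    replace = TRUE)
      fam <- sample(1:3, n_ev, replace = TRUE)
      data.frame(kind = kinds, position = pos, length = len,
                 element_label = paste0("synTy", fam),
                 family = fam, stringsAsFactors = FALSE)
    }

    group_plants <- lapply(groups, function(g) plan_group())

    strains <- list()
    plants_all <- NULL
    snps_all <- NULL
    nruns_all <- NULL
    ann <- NULL
    for (gi in seq_along(groups)) {
      gp <- group_plants[[gi]]
      # reference annotations: deleted intervals are synthetic Ty copies;
      # optionally a solo-LTR flanks each insertion point
      del <- gp[gp$kind == "deletion", , drop = FALSE]
      if (nrow(del))
        ann <- rbind(ann, data.frame(
          chrom_id = reference$chrom_id, start = del$position,
          end = del$position + del$length,
          feature_class = paste0("Ty", del$family),
          name = paste0(del$element_label, "_g", gi, "_",
                        seq_len(nrow(del))),
          stringsAsFactors = FALSE))
      if (ltr_near_insertions) {
        ins <- gp[gp$kind == "insertion", , drop = FALSE]
        if (nrow(ins))
          ann <- rbind(ann, data.frame(
            chrom_id = reference$chrom_id, start = ins$position + 60,
            end = ins$position + 360,
            feature_class = "Ty1ltr",
            name = paste0("synLTR_g", gi, "_", seq_len(nrow(ins))),
            stringsAsFactors = FALSE))
      }
      for (si in groups[[gi]]) {
        sid <- paste0("s", si)
        ds <- derive_strain(reference, gp[, c("kind", "position", "length",
                                              "element_label")],
                            snp_rate = snp_rate,
                            n_runs = list(n = n_runs,
                                          min_len = n_run_length[1],
                                          max_len = n_run_length[2]),
                            seed = NULL, strain_id = sid, library = lib)
        strains[[sid]] <- ds$chrom
        plants_all <- rbind(plants_all, ds$truth$plants)
        snps_all <- rbind(snps_all, ds$truth$snps)
        nruns_all <- rbind(nruns_all, ds$truth$n_runs)
      }
    }

    params <- list(seed = seed, n_strains = n_strains, ref_length = ref_length,
                   n_insertions = n_insertions, n_deletions = n_deletions,
                   element_length = element_length, snp_rate = snp_rate,
                   n_runs = n_runs, n_run_length = n_run_length,
                   clades = lapply(groups, identity),
                   ltr_near_insertions = ltr_near_insertions, margin = margin)
    list(reference = reference, strains = strains,
         truth = list(seed = seed, plants = plants_all, snps = snps_all,
                      n_runs = nruns_all),
         annotations = ann, params = params)
  })
}

#' Write / read a truth log (JSON)
#'
#' @param truth the `truth` element of [simulate_strain_set()] (or
#'   [derive_strain()]).
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("plants", "snps", "n_runs"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.data.frame(x[[nm]])
  x
}

#' Write reference annotations as GFF3
#'
#' @param ann annotation data.frame (0-based half-open coordinates).
#' @param path output file.
#' @export
write_annotations_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(ann) && nrow(ann)) {
    lines <- sprintf("%s\tmobscan\t%s\t%d\t%d\t.\t+\t.\tName=%s",
                     ann$chrom_id, ann$feature_class,
                     as.integer(ann$start + 1), as.integer(ann$end),
                     ann$name)
    writeLines(lines, con)
  }
  invisible(path)
}
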