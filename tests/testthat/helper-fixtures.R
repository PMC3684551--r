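# shared fixture builders and independent oracles

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute a fraction of positions (never to the same base)
mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  k <- rbinom(1, n, rate)
  if (k > 0) {
    pos <- sample(n, k)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

plant_n_run <- function(s, start, len) {
  substr(s, start + 1, start + len) <- strrep("N", len)
  s
}

# independent binary XOR on doubles, by bit expansion
bits_of <- function(x, w) as.integer(floor(x / 2^(0:(w - 1))) %% 2)
xor_dbl <- function(a, b, w) {
  sum(abs(bits_of(a, w) - bits_of(b, w)) * 2^(0:(w - 1)))
}

# naive O(n*m) all-window matcher: the Phase-1 oracle
naive_common <- function(ref, query, L) {
  nwin <- function(s) max(0, nchar(s) - L + 1)
  wins <- function(s) {
    n <- nwin(s)
    if (n == 0) return(character(0))
    substring(s, 1:n, L:(L + n - 1))
  }
  rw <- wins(ref)
  qw <- wins(query)
  rvalid <- !grepl("N", rw, fixed = TRUE)
  qvalid <- !grepl("N", qw, fixed = TRUE)
  j <- integer(0); occs <- list()
  for (q in seq_along(qw)) {
    if (!qvalid[q]) next
    hits <- which(rvalid & rw == qw[q]) - 1L
    if (length(hits)) {
      j <- c(j, q - 1L)
      occs[[length(occs) + 1L]] <- hits
    }
  }
  list(j = j, occs = occs,
       stats = list(total = length(qw), valid = sum(qvalid),
                    common = length(j),
                    multi = sum(vapply(occs, length, integer(1)) >= 2)))
}

# hand-built conservation map for classifier tests
make_cmap <- function(df, ref_length, query_length, L = 32L,
                      ref_id = "ref", query_id = "q") {
  attr(df, "ref_id") <- ref_id
  attr(df, "query_id") <- query_id
  attr(df, "chrom_id") <- "chr"
  attr(df, "ref_length") <- ref_length
  attr(df, "query_length") <- query_length
  attr(df, "L") <- L
  class(df) <- c("conservation_map", "data.frame")
  df
}

# per-base interval coverage, the brute-force oracle for interval algebra
coverage_vector <- function(iv, len) {
  v <- logical(len)
  for (k in seq_len(nrow(iv)))
    if (iv$end[k] > iv$start[k]) v[(iv$start[k] + 1):iv$end[k]] <- TRUE
  v
}

# a reference/query pair with one planted insertion, no other differences
pair_with_insertion <- function(ref_len, ins_pos, ins_len) {
  ref <- rand_seq(ref_len)
  ins <- rand_seq(ins_len)
  query <- paste0(substr(ref, 1, ins_pos), ins,
                  substr(ref, ins_pos + 1, ref_len))
  list(ref = ref, query = query, ins_start = ins_pos,
       ins_end = ins_pos + ins_len)
}

seg_coverage <- function(m2) {
  if (nrow(m2) == 0) return(0)
  sum(m2$query_end - m2$query_start)
}
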