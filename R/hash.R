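#' Hashing configuration for L-gram anchoring
#'
#' Each base A, C, G, T is assigned a pseudo-random `w`-bit word (the base
#' code). The hash of an L-gram `t = t[1]..t[L]` is the XOR of cyclically
#' rotated base codes,
#' `h(t) = s^(L-1)(h_t1) XOR s^(L-2)(h_t2) XOR ... XOR s(h_t(L-1)) XOR h_tL`,
#' where `s` rotates a `w`-bit word one position to the left. This cyclic
#' polynomial scheme admits a constant-time rolling update when the window
#' slides one base to the right, which is what makes whole-chromosome
#' anchoring linear-time on average.
#'
#' Base codes are drawn once from a fixed, documented seed so that runs are
#' reproducible; their exact values are irrelevant to correctness because
#' every hash hit is verified by direct base-string comparison before it can
#' become a common L-gram.
#'
#' @param L gram length in bases (default 32).
#' @param w word width in bits; any width from 1 to 53 is supported (values
#'   stay exactly representable as doubles), default 32.
#' @param seed integer seed for the base-code draw.
#' @return an object of class `hash_config` with elements `L`, `w`, `codes`
#'   (named numeric vector for A, C, G, T) and `seed`.
#' @export
#' @examples
#' cfg <- hash_config(L = 8)
#' hash_lgram("ACGTACGT", cfg)
hash_config <- function(L = 32L, w = 32L, seed = 1009L) {
  L <- as.integer(L)
  w <- as.integer(w)
  if (is.na(L) || L < 1L) stop("L must be a positive integer")
  if (is.na(w) || w < 1L || w > 53L) stop("word width w must be in 1..53")
  codes <- with_seed(seed, {
    repeat {
      v <- vapply(1:4, function(k) {
        bits <- sample(c(0, 1), w, replace = TRUE)
        sum(bits * 2^(seq_len(w) - 1))
      }, numeric(1))
      if (length(unique(v)) == 4L && all(v > 0)) break
    }
    v
  })
  names(codes) <- c("A", "C", "G", "T")
  structure(list(L = L, w = w, codes = codes, seed = as.integer(seed)),
            class = "hash_config")
}

#' @export
print.hash_config <- function(x, ...) {
  cat(sprintf("<hash_config> L = %d, w = %d bits, base-code seed = %d\n",
              x$L, x$w, x$seed))
  invisible(x)
}

#' Cyclic left rotation of a w-bit word
#'
#' Shifts the bit string left by `i` positions, re-entering the leftmost bit
#' at the right; rotation by any multiple of `w` is the identity.
#'
#' @param x non-negative numeric vector of `w`-bit values.
#' @param i rotation count(s), non-negative; reduced modulo `w`.
#' @param w word width in bits (1..53).
#' @return the rotated value(s).
#' @export
#' @examples
#' rotate_left(strtoi("10110", base = 2), 1, w = 5)  # 01101 -> 13
#' rotate_left(strtoi("10110", base = 2), 2, w = 5)  # 11010 -> 26
rotate_left <- function(x, i, w) {
  w <- as.integer(w)
  if (any(x < 0) || any(x >= 2^w)) stop("x must be a w-bit value")
  cpp_rotate_left(as.numeric(x), as.numeric(i), w)
}

#' Hash one L-gram
#'
#' Direct evaluation of the cyclic-polynomial hash. The gram must be exactly
#' `cfg$L` bases long and free of unresolved bases (N); windows containing N
#' are never hashed anywhere in the pipeline.
#'
#' @param t a base string of length `cfg$L` over \{A,C,G,T\}.
#' @param cfg a [hash_config()].
#' @return the hash value as a double-precision integer.
#' @export
hash_lgram <- function(t, cfg = hash_config()) {
  if (nchar(t) != cfg$L)
    stop(sprintf("gram has %d bases but L = %d", nchar(t), cfg$L))
  if (grepl("[^ACGT]", t))
    stop("gram contains a base outside {A,C,G,T}; windows with N are not hashed")
  cpp_hash_lgram(t, cfg$codes, cfg$w)
}

#' Rolling hash update
#'
#' Given the hash of a window whose first base is `out_base`, returns the hash
#' of the window shifted one base to the right with `in_base` appended:
#' `h(t') = s(h(t)) XOR s^L(h_out) XOR h_in`. Equals [hash_lgram()] of the
#' shifted window.
#'
#' @param h hash of the current window.
#' @param out_base the base leaving the window (its first base).
#' @param in_base the base entering the window.
#' @param cfg a [hash_config()].
#' @return the updated hash value.
#' @export
roll_hash <- function(h, out_base, in_base, cfg = hash_config()) {
  if (!out_base %in% c("A", "C", "G", "T") || !in_base %in% c("A", "C", "G", "T"))
    stop("rolled bases must be in {A,C,G,T}")
  cpp_roll(h, out_base, in_base, cfg$L, cfg$codes, cfg$w)
}

#' Hash every window of a sequence
#'
#' Computes the hash of every length-L window. Windows overlapping an N (or
#' any non-ACGT character) are `NA`: only maximal ACGT runs of length at least
#' L are scanned. `method = "rolling"` chains the constant-time update along
#' each run; `method = "direct"` evaluates the full summation formula
#' independently for every window. The two must agree everywhere, which is
#' used as a correctness check of the rolling update.
#'
#' @param seq a base string or [chromosome_seq()].
#' @param cfg a [hash_config()].
#' @param method `"rolling"` or `"direct"`.
#' @return numeric vector of length `nchar(seq) - L + 1` (empty if shorter),
#'   with `NA` at invalid windows.
#' @export
hash_windows <- function(seq, cfg = hash_config(),
                         method = c("rolling", "direct")) {
  method <- match.arg(method)
  s <- if (inherits(seq, "chromosome_seq")) seq$seq else seq
  cpp_hash_windows(s, cfg$L, cfg$codes, cfg$w, method == "rolling")
}
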