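# Internal numeric / RNG plumbing shared by all modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' functions never disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Deterministic child seed from a master seed and a hierarchical key
#'
#' Derives per-(sample, replicate, genome, contig, stage) seeds so that
#' simulation output does not depend on execution order.  A simple
#' 31-ary string fold over the key, offset by the master seed, modulo a
#' Mersenne prime; all arithmetic stays below 2^53 so the result is
#' exact in double precision and identical across platforms.
#'
#' @param master integer master seed.
#' @param ... key components (coerced to character).
#' @return a positive integer seed < 2^31.
#' @export
#' @examples
#' child_seed(42, "s1", 1, "genomeA")
child_seed <- function(master, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  p <- 2147483629
  h <- (abs(as.double(master)) + 11) %% p
  for (b in utf8ToInt(key)) h <- (h * 31 + b + 7) %% p
  # one extra mixing round so short keys differing in one char diverge
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% p
  as.integer(h %% 2147483646) + 1L
}

#' Largest-remainder (Hamilton) integer apportionment
#'
#' Distributes `total` integer units proportionally to non-negative
#' `weights` so the parts sum to `total` exactly.  Ties on the
#' fractional remainder are broken by input order.
#'
#' @param weights non-negative numeric vector, not all zero (unless total is 0).
#' @param total non-negative integer to distribute.
#' @return integer vector, same length as `weights`, summing to `total`.
#' @export
#' @examples
#' largest_remainder(c(500, 300, 200), 7)  # 4 2 1
largest_remainder <- function(weights, total) {
  stopifnot(is.numeric(weights), length(weights) >= 1, all(weights >= 0),
            length(total) == 1, total >= 0)
  total <- as.integer(round(total))
  if (total == 0L) return(integer(length(weights)))
  if (sum(weights) == 0)
    stop("largest_remainder(): all weights are zero but total > 0")
  shares <- weights / sum(weights) * total
  base <- as.integer(floor(shares))
  left <- total - sum(base)
  if (left > 0L) {
    frac <- shares - base
    take <- order(-frac, seq_along(frac))[seq_len(left)]
    base[take] <- base[take] + 1L
  }
  base
}

# Phred+33 encoding helpers -------------------------------------------------

phred_to_char <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 0L), 93L)
  intToUtf8(q + 33L, multiple = FALSE)
}

#' Linear quality ramp string for a read of given length
#' @noRd
quality_ramp <- function(read_length, q_start, q_end) {
  if (read_length == 1L) return(phred_to_char(q_start))
  phred_to_char(seq(q_start, q_end, length.out = read_length))
}

# Sequence helpers ----------------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Stop with a classed error (keeps error classes grep-able in tests)
#' @noRd
mm_stop <- function(class, ...) {
  stop(structure(class = c(class, "metamock_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
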