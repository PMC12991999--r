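# Shared constants and small internal helpers.

#' @importFrom rlang .data
#' @importFrom stats median p.adjust rhyper rnorm runif sd setNames
#' @importFrom utils head
NULL

# The 20 standard amino acids.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Interior amino-acid frequency profile used by the CDR3 generator.
# Glycine/serine-heavy, reflecting typical junctional composition of beta-chain
# CDR3s; exact values are a modelling choice, only the relative skew matters.
CDR3_AA_PROFILE <- c(
  A = 0.055, C = 0.005, D = 0.045, E = 0.050, F = 0.035,
  G = 0.105, H = 0.020, I = 0.030, K = 0.030, L = 0.070,
  M = 0.010, N = 0.040, P = 0.045, Q = 0.055, R = 0.060,
  S = 0.130, T = 0.075, V = 0.045, W = 0.010, Y = 0.085
)

# Default V/J segment pools (allele-stripped names, beta chain).
DEFAULT_TRBV <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV5-6", "TRBV6-1", "TRBV7-2",
                  "TRBV7-9", "TRBV9", "TRBV11-2", "TRBV12-3", "TRBV14-1",
                  "TRBV15", "TRBV19", "TRBV20-1", "TRBV27", "TRBV28",
                  "TRBV29-1", "TRBV30")
DEFAULT_TRBJ <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5",
                  "TRBJ1-6", "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4",
                  "TRBJ2-5", "TRBJ2-6", "TRBJ2-7")

#' Check CDR3 amino-acid strings
#'
#' A valid CDR3 here is a non-empty, uppercase string over the 20 standard
#' amino-acid letters (stop codons `*`, frameshift `_`, gaps and lowercase all
#' fail).
#'
#' @param x Character vector.
#' @return Logical vector, `TRUE` where `x` is a valid CDR3 string.
#' @export
#' @examples
#' valid_cdr3(c("CASSLGQYF", "CASS*F", "", "casslf"))
valid_cdr3 <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

#' Strip allele suffixes from gene-segment names
#'
#' Reduces allele-level calls such as `"TRBV15*01"` to segment level
#' (`"TRBV15"`) so usage tallies aggregate at the level gene-usage figures
#' are reported at.
#'
#' @param x Character vector of gene calls.
#' @return Character vector of segment-level names.
#' @export
#' @examples
#' strip_allele(c("TRBV15*01", "TRAV2", "TRBJ2-7*02"))
strip_allele <- function(x) {
  sub("\\*.*$", "", x)
}

# Deterministic 31-bit string hash, used to derive independent per-sample /
# per-subject RNG seeds from a master seed. Kept below 2^31 - 1 so it is a
# valid R integer seed on every platform.
hash31 <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 17
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a child seed from a master seed and a string label.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + hash31(label)) %% 2147483647)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
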