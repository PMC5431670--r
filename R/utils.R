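# Internal helpers shared across modules.

#' The 20 standard amino acids, one-letter code
#'
#' Alphabet used for all protein sequences; positions carrying any other
#' letter (X, B, Z, U, ...) are treated as masked.
#'
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Typed error, so callers/tests can distinguish failure modes.
sav_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "savshift_error", "error")))
}

#' @importFrom stats runif rnorm sd
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Stable sub-seed from a master seed and a string key, so adding records to
# a simulation does not reshuffle the streams of existing ones.  Polynomial
# rolling hash mod a Mersenne prime, kept below 2^31.
stable_seed <- function(seed, key) {
  stopifnot(is.character(key), length(key) == 1L)
  p <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed %% p)
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% p
  }
  as.integer(h)
}

# Normalise a proteome argument (named character vector or AAStringSet)
# to a named character vector of upper-case sequences.
as_proteome <- function(x) {
  if (methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) {
    sav_error("savshift_error_bad_input",
              "a proteome must be a named character vector or an AAStringSet")
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    sav_error("savshift_error_bad_input", "every protein sequence needs an id")
  }
  if (anyDuplicated(names(x))) {
    sav_error("savshift_error_bad_input", "duplicated protein ids in proteome")
  }
  if (any(nchar(x) == 0L)) {
    sav_error("savshift_error_bad_input", "empty protein sequence")
  }
  toupper(x)
}

#' @importFrom methods is
NULL
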