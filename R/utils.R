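# Internal helpers: seeded evaluation, sequence codes, hashing.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic derived seeds, kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 7919 + k) %% 2147483647L
}

# Base coding: A=0, C=1, G=2, T=3, anything else 4. Stored as raw vectors so a
# 30-Mb chromosome costs 30 MB.
.code_lookup <- local({
  tbl <- rep(4L, 256L)
  tbl[utf8ToInt("A")] <- 0L
  tbl[utf8ToInt("C")] <- 1L
  tbl[utf8ToInt("G")] <- 2L
  tbl[utf8ToInt("T")] <- 3L
  tbl
})

seq_to_code <- function(s) {
  as.raw(.code_lookup[utf8ToInt(s)])
}

code_to_seq <- function(code) {
  intToUtf8(c(65L, 67L, 71L, 84L, 78L)[as.integer(code) + 1L])
}

#' Reverse complement of DNA strings
#'
#' Plain-character convenience used for end-motif bookkeeping; ambiguous
#' bases map to `N`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

# Discretized Laplace sampler (1-bp resolution) for the mono-nucleosomal
# fragment-length component.
rdlaplace <- function(n, location, scale) {
  u <- runif(n) - 0.5
  as.integer(round(location - scale * sign(u) * log1p(-2 * abs(u))))
}

# Stable md5 of an R object through its canonical JSON form.
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
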