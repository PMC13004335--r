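# Internal helpers: key construction, deterministic ordering, seeded RNG.

# Separator constants. Gene symbols never contain "|" and cell-type labels
# never contain "->"; both are validated at ingest.
.PAIR_SEP <- "|"
.COMM_SEP <- "->"
.COMPLEX_SEP <- "_"

pairKey <- function(ligand, receptor) {
  paste(ligand, receptor, sep = .PAIR_SEP)
}

splitPairKey <- function(key) {
  parts <- strsplit(key, .PAIR_SEP, fixed = TRUE)
  data.frame(
    ligand = vapply(parts, `[`, character(1), 1L),
    receptor = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

commKey <- function(source, target) {
  paste(source, target, sep = .COMM_SEP)
}

splitCommKey <- function(key) {
  parts <- strsplit(key, .COMM_SEP, fixed = TRUE)
  data.frame(
    source = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Locale-independent ordering (C collation) so output tables are
# byte-identical across platforms.
radixOrder <- function(...) {
  order(..., method = "radix")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage random seed from a global seed
#'
#' Fans a single run-level seed out into independent substreams, one per
#' named pipeline stage, by stable hashing of the stage name. Adding a new
#' stage therefore never perturbs the randomness consumed by existing
#' stages. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"permtest"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(1L, "permtest")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 7919) %% 2147483647)
}

# Checks a character vector for a forbidden separator; errors naming `what`.
assertNoSep <- function(x, sep, what) {
  bad <- grepl(sep, x, fixed = TRUE)
  if (any(bad)) {
    stop(sprintf("%s labels must not contain '%s': %s",
                 what, sep, paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}
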