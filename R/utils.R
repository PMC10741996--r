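#' Evaluate code with a temporary RNG seed
#'
#' Sets the R random seed for the duration of `code` and restores the
#' previous RNG state afterwards, so library calls do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit string hash (polynomial, mod 2^31 - 1).  Used to derive
# per-gene child seeds and config fingerprints; platform-independent and
# stable across sessions, unlike e.g. serialization-based digests.
stable_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  bytes <- utf8ToInt(enc2utf8(s))
  acc <- 0
  for (b in bytes) acc <- (acc * 31 + b) %% 2147483647
  acc
}

#' Derive a per-gene child seed from a root seed
#'
#' Child seeds depend only on the root seed and the gene identifier, never on
#' iteration order, so subsetting targets or changing worker counts cannot
#' change any gene's result.  `stream` separates independent uses for the
#' same gene (model fit vs. the two enrichment nulls).
#'
#' @param root_seed integer root seed for the whole run.
#' @param gene gene identifier.
#' @param stream small integer tag for independent substreams.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
gene_seed <- function(root_seed, gene, stream = 0L) {
  h <- stable_hash(paste0(gene, "#", stream))
  as.integer(1 + (as.numeric(root_seed) + h) %% 2147483645)
}

# Fingerprint of an arbitrary (nestable, name-value) configuration object.
config_hash <- function(config) {
  txt <- paste(deparse(config, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  sprintf("%08x", stable_hash(txt))
}

# Commented provenance line written at the top of every table the tool emits.
tool_header <- function(config_hash = "none") {
  ver <- as.character(utils::packageVersion("rfgsea"))
  sprintf("# rfgsea %s\tconfig=%s", ver, config_hash)
}

# write a data.frame as TSV under a commented provenance header
write_tsv_with_header <- function(df, path, config_hash = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tool_header(config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
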