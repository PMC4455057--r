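# Internal helpers shared across modules.

# Conventional taxonomic ranks, highest first. Lineages may skip ranks but
# must never invert this order.
RANK_ORDER <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed for a named stage from a master seed.
# Keeps results independent of the order in which stages consume randomness.
substream_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 69621 + index * 7919) %%
               2147483587) + 1L
}

#' Parse a "rank:name;rank:name" lineage string
#'
#' @return named character vector; names are ranks in descending order.
#' @noRd
parse_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  if (!length(parts)) stop("empty lineage string")
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed lineage element: ", parts[bad][1])
  out <- vapply(kv, function(p) trimws(p[2]), "")
  names(out) <- vapply(kv, function(p) trimws(tolower(p[1])), "")
  ranks <- match(names(out), RANK_ORDER)
  if (anyNA(ranks)) stop("unknown lineage rank: ",
                         names(out)[is.na(ranks)][1])
  if (any(diff(ranks) <= 0)) stop("lineage ranks out of order: ", x)
  out
}

format_lineage <- function(lin) {
  paste(paste0(names(lin), ":", lin), collapse = ";")
}

# Vectorised lineage lookup table: organism_id -> named character vector.
lineage_table <- function(taxa) {
  out <- lapply(taxa$lineage, parse_lineage)
  names(out) <- taxa$organism_id
  out
}

domain_of <- function(taxa) {
  stats::setNames(taxa$domain, taxa$organism_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
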