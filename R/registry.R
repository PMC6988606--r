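# Asset registry paths: the human-readable identifiers used everywhere else.
#
# Grammar:  genome/asset[.seek_key][:tag]
# Tokens (genome, asset, seek_key, tag) are drawn from [A-Za-z0-9_-]; they
# become filesystem path components verbatim, which is why '/', ':', '.' and
# whitespace are excluded. An absent tag means the literal tag "default".

REGISTRY_TOKEN_RE <- "[A-Za-z0-9_-]+"

#' Parse an asset registry path
#'
#' Registry paths identify assets as `genome/asset[.seek_key][:tag]`, where
#' the genome acts as a namespace, the tag names a version of the asset, and
#' the optional seek key addresses one file inside the asset directory.
#' A missing tag is filled with the literal tag name `"default"`.
#'
#' @param s A single registry path string, e.g. `"hg38/fasta:v2"` or
#'   `"hg38/fasta.chrom_sizes"`.
#' @return An object of class `asset_registry_path`: a list with elements
#'   `genome`, `asset`, `tag` and `seek_key` (`NULL` when absent).
#' @examples
#' parse_registry_path("hg38/bowtie2_index")
#' parse_registry_path("hg38/fasta.chrom_sizes:v2")
#' @seealso [format_registry_path()]
#' @export
parse_registry_path <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    abort_parse("registry path must be a single non-empty string")
  }
  tok <- REGISTRY_TOKEN_RE
  re <- sprintf("^(%s)/(%s)(\\.(%s))?(:(%s))?$", tok, tok, tok, tok)
  m <- regmatches(s, regexec(re, s))[[1]]
  if (length(m) == 0L) {
    abort_parse(sprintf(
      "malformed registry path '%s' (expected genome/asset[.seek_key][:tag], tokens [A-Za-z0-9_-])",
      s
    ))
  }
  new_registry_path(
    genome = m[2L],
    asset = m[3L],
    tag = if (nzchar(m[7L])) m[7L] else "default",
    seek_key = if (nzchar(m[5L])) m[5L] else NULL
  )
}

new_registry_path <- function(genome, asset, tag = "default", seek_key = NULL) {
  for (x in c(genome, asset, tag, seek_key)) {
    if (!grepl(sprintf("^%s$", REGISTRY_TOKEN_RE), x)) {
      abort_parse(sprintf("invalid registry path component '%s'", x))
    }
  }
  structure(
    list(genome = genome, asset = asset, tag = tag, seek_key = seek_key),
    class = "asset_registry_path"
  )
}

#' Format an asset registry path
#'
#' Inverse of [parse_registry_path()]: renders the canonical form
#' `genome/asset[.seek_key]:tag` (the tag is always printed, so
#' `format(parse(s))` is the canonical form of `s`).
#'
#' @param p An `asset_registry_path` object.
#' @return A single string.
#' @export
format_registry_path <- function(p) {
  stopifnot(inherits(p, "asset_registry_path"))
  key <- if (is.null(p$seek_key)) "" else paste0(".", p$seek_key)
  sprintf("%s/%s%s:%s", p$genome, p$asset, key, p$tag)
}

#' @export
format.asset_registry_path <- function(x, ...) format_registry_path(x)

#' @export
print.asset_registry_path <- function(x, ...) {
  cat("<registry path> ", format_registry_path(x), "\n", sep = "")
  invisible(x)
}

# Coerce a string or registry-path object to a registry path.
as_registry_path <- function(x) {
  if (inherits(x, "asset_registry_path")) x else parse_registry_path(x)
}
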