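# Asset identity and traceability: content digests, build logs, and canonical
# recipe serialization.
#
# Digest construction (bit-exact contract, documented so that independent
# implementations can reproduce it):
#   1. Enumerate every regular file under the asset directory, recursively,
#      including hidden files; express each as a relative path with '/'
#      separators. Exclude any file whose *basename* starts with "_build_log"
#      (the provenance record itself, so the digest can be stored inside it).
#   2. Sort the relative paths bytewise (C collation).
#   3. For each file compute the SHA-256 of its raw bytes (no newline or
#      encoding normalization; assets are binary-opaque).
#   4. Concatenate the lines "<relpath>\t<sha256hex>\n" in sorted order and
#      take the SHA-256 of that UTF-8 string. The lowercase 64-hex result is
#      the asset digest. An empty directory therefore digests to
#      SHA-256("") = e3b0c44298fc1c149afbf4c8996fb92427ae41e4649b934ca495991b7852b855.
#
# The digest depends only on relative paths and contents: it is invariant to
# the directory's absolute location, its own name, file timestamps, and
# enumeration order.

BUILD_LOG_FILENAME <- "_build_log.yaml"

sha256_file <- function(path) {
  digest::digest(path, algo = "sha256", file = TRUE)
}

sha256_string <- function(x) {
  digest::digest(x, algo = "sha256", serialize = FALSE)
}

#' Compute the content digest of an asset directory
#'
#' A location- and order-independent SHA-256 over the sorted sequence of
#' (relative path, per-file SHA-256) pairs. Files named `_build_log*` are
#' excluded so the digest can be recorded inside the build log. See the
#' source header / methods vignette for the bit-exact construction.
#'
#' @param asset_dir Path to an existing directory.
#' @return Lowercase 64-character hex string.
#' @export
compute_asset_digest <- function(asset_dir) {
  if (!dir.exists(asset_dir)) {
    refassets_abort(sprintf("asset directory '%s' does not exist", asset_dir),
                    "refassets_missing_error", level = "asset")
  }
  files <- list.files(asset_dir, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  files <- files[!startsWith(basename(files), "_build_log")]
  # list.files returns sorted results, but collation is locale-dependent;
  # force a bytewise order so the digest is stable across locales.
  files <- files[order(files, method = "radix")]
  lines <- character(length(files))
  for (i in seq_along(files)) {
    fp <- file.path(asset_dir, files[i])
    if (!file.exists(fp) || dir.exists(fp)) next
    h <- tryCatch(sha256_file(fp), error = function(e) NULL)
    if (is.null(h)) {
      refassets_abort(sprintf("cannot read file '%s' while computing digest", fp),
                      "refassets_error")
    }
    lines[i] <- paste0(files[i], "\t", h, "\n")
  }
  sha256_string(paste(lines, collapse = ""))
}

#' Abbreviate a digest for display
#'
#' Full digests are stored everywhere; listings show the first 32 hex
#' characters.
#'
#' @param digest A 64-hex digest string (vectorized).
#' @return Truncated digest string(s).
#' @export
format_digest <- function(digest) substr(digest, 1L, 32L)

#' Create a build log record
#'
#' The provenance record written alongside every built asset: the inputs and
#' their content digests, tool versions, timestamps, and the final asset
#' digest.
#'
#' @param registry_path Canonical registry path string of the built asset.
#' @param recipe_name,recipe_version Recipe identity.
#' @param inputs Named list: input name -> list(path=, digest=).
#' @param software_versions Named list of tool -> version string.
#' @param started,finished Timestamps as ISO-8601 UTC strings.
#' @param asset_digest Digest of the asset directory at write time.
#' @return An object of class `build_log`.
#' @export
build_log <- function(registry_path, recipe_name, recipe_version,
                      inputs = list(), software_versions = list(),
                      started, finished, asset_digest) {
  structure(
    list(
      registry_path = registry_path,
      recipe_name = recipe_name,
      recipe_version = recipe_version,
      inputs = inputs,
      software_versions = software_versions,
      started = started,
      finished = finished,
      asset_digest = asset_digest
    ),
    class = "build_log"
  )
}

utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a build log into an asset directory
#'
#' Stored as YAML under the fixed, digest-excluded filename
#' `_build_log.yaml`.
#'
#' @param asset_dir Asset directory.
#' @param log A `build_log` object.
#' @return The path of the written file, invisibly.
#' @export
write_build_log <- function(asset_dir, log) {
  stopifnot(inherits(log, "build_log"))
  path <- file.path(asset_dir, BUILD_LOG_FILENAME)
  writeLines(yaml::as.yaml(unclass(log), indent = 2L), path, sep = "")
  invisible(path)
}

#' Read the build log of an asset directory
#'
#' @param asset_dir Asset directory.
#' @return A `build_log` object.
#' @export
read_build_log <- function(asset_dir) {
  path <- file.path(asset_dir, BUILD_LOG_FILENAME)
  if (!file.exists(path)) {
    refassets_abort(
      sprintf("no provenance: '%s' has no %s", asset_dir, BUILD_LOG_FILENAME),
      "refassets_missing_error", level = "log"
    )
  }
  x <- yaml::yaml.load_file(path)
  structure(x[c("registry_path", "recipe_name", "recipe_version", "inputs",
                "software_versions", "started", "finished", "asset_digest")],
            class = "build_log")
}

#' Serialize a recipe canonically
#'
#' Deterministic, key-sorted YAML rendering: equal recipes serialize to
#' byte-identical text. This is the representation served by the archive
#' server's recipe endpoint.
#'
#' @param recipe A `recipe` object (see [get_recipe()]).
#' @return A single string of YAML text.
#' @export
serialize_recipe <- function(recipe) {
  stopifnot(inherits(recipe, "recipe"))
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x)) {
      x <- x[order(names(x), method = "radix")]
      lapply(x, sort_rec)
    } else if (is.list(x)) {
      lapply(x, sort_rec)
    } else {
      x
    }
  }
  yaml::as.yaml(sort_rec(unclass(recipe)), indent = 2L)
}
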