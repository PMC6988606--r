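# Client side of the archive server API: discover remote assets, download
# archives, verify integrity, unpack, and register locally.

http_get <- function(url) {
  h <- curl::new_handle()
  curl::handle_setopt(h, timeout = 60L, followlocation = TRUE)
  curl::curl_fetch_memory(url, handle = h)
}

http_get_json <- function(url) {
  res <- http_get(url)
  body <- rawToChar(res$content)
  parsed <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                     error = function(e) NULL)
  list(status = res$status_code, body = parsed, raw = body)
}

#' List genomes and assets available on remote servers
#'
#' Queries each server's `/v2/assets` endpoint and unions the results; on
#' conflicts the first-listed server wins for that genome. Individual server
#' failures are tolerated as long as at least one server responds.
#'
#' @param servers Character vector of server base URLs, in precedence order.
#' @return Named list: genome -> character vector of asset names, with an
#'   attribute `failures` (named character vector of per-server error
#'   messages, possibly empty).
#' @export
list_remote <- function(servers) {
  if (!length(servers)) {
    abort_usage("no genome servers configured")
  }
  out <- list()
  failures <- character()
  ok <- FALSE
  for (s in servers) {
    res <- tryCatch(http_get_json(paste0(s, "/v2/assets")),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[[s]] <- res
      next
    }
    if (!identical(res$status, 200L) || !is.list(res$body)) {
      failures[[s]] <- sprintf("HTTP %s", res$status)
      next
    }
    ok <- TRUE
    for (g in names(res$body)) {
      if (is.null(out[[g]])) {
        out[[g]] <- as.character(unlist(res$body[[g]]))
      }
    }
  }
  if (!ok) {
    abort_network(paste0(
      "no genome server reachable:\n",
      paste(sprintf("  %s: %s", names(failures), failures), collapse = "\n")
    ))
  }
  attr(out, "failures") <- failures
  out
}

# Query one server for asset attributes. Returns list(attrs=) on success,
# list(missing_level=, message=) on a structured 404, or
# list(network=message) when unreachable.
fetch_attributes <- function(server, p) {
  url <- sprintf("%s/v2/asset/%s/%s/attributes?tag=%s",
                 server, p$genome, p$asset, p$tag)
  res <- tryCatch(http_get_json(url), error = function(e) conditionMessage(e))
  if (is.character(res)) return(list(network = res))
  if (identical(res$status, 200L)) return(list(attrs = res$body))
  if (identical(res$status, 404L) && is.list(res$body)) {
    return(list(missing_level = res$body$level %||% "asset",
                message = res$body$error %||% "not found"))
  }
  list(network = sprintf("HTTP %s from %s", res$status, url))
}

#' Pull a remote asset
#'
#' Downloads the asset's tarball from the first configured server that has
#' it, verifies the tarball bytes against the advertised archive digest,
#' unpacks it, verifies the unpacked tree against the advertised asset
#' digest, moves it into `{genome_folder}/{genome}/{asset}/{tag}/`, and
#' registers it (seek keys and digest taken from the server's attributes).
#' On any failure all temporary files are removed and the configuration is
#' unchanged.
#'
#' @param config A `genome_config` with at least one server URL (or pass
#'   `servers` explicitly).
#' @param path Registry path (string or parsed); a seek-key suffix is not
#'   allowed.
#' @param servers Character vector of server base URLs; defaults to the
#'   config's `genome_servers`.
#' @param force Re-pull over an existing local tag.
#' @return A list with elements `config` (updated `genome_config`) and
#'   `entry` (the new tag entry).
#' @export
pull_asset <- function(config, path, servers = config$genome_servers,
                       force = FALSE) {
  p <- as_registry_path(path)
  if (!is.null(p$seek_key)) {
    abort_usage("registry path for pull must not carry a seek key")
  }
  if (!length(servers)) {
    abort_usage("no genome servers configured; cannot pull")
  }
  existing <- config$genomes[[p$genome]]$assets[[p$asset]]$tags[[p$tag]]
  if (!is.null(existing) && !force) {
    abort_exists(sprintf(
      "asset '%s/%s:%s' already exists locally; use force to re-pull",
      p$genome, p$asset, p$tag
    ))
  }

  attrs <- NULL
  chosen <- NULL
  network_failures <- character()
  miss <- NULL
  for (s in servers) {
    res <- fetch_attributes(s, p)
    if (!is.null(res$attrs)) {
      attrs <- res$attrs
      chosen <- s
      break
    }
    if (!is.null(res$missing_level)) {
      miss <- res  # server reachable, asset unknown there
    } else {
      network_failures[[s]] <- res$network
    }
  }
  if (is.null(attrs)) {
    if (!is.null(miss)) {
      abort_missing(sprintf("remote: %s", miss$message), miss$missing_level)
    }
    abort_network(paste0(
      "no genome server reachable:\n",
      paste(sprintf("  %s: %s", names(network_failures), network_failures),
            collapse = "\n")
    ))
  }

  tag_dir <- file.path(config$genome_folder, p$genome, p$asset, p$tag)
  parent <- dirname(tag_dir)
  created_dirs <- character()
  d <- parent
  while (!dir.exists(d)) {
    created_dirs <- c(d, created_dirs)
    d <- dirname(d)
  }
  if (length(created_dirs)) dir.create(parent, recursive = TRUE)

  tmp_tar <- tempfile(fileext = ".tgz")
  unpack_dir <- tempfile(pattern = sprintf(".pull_%s_", p$tag), tmpdir = parent)
  ok <- FALSE
  on.exit({
    unlink(tmp_tar)
    if (!ok) {
      unlink(unpack_dir, recursive = TRUE)
      # roll back directory levels this pull created
      for (cd in rev(created_dirs)) {
        if (dir.exists(cd) &&
            !length(list.files(cd, all.files = TRUE, no.. = TRUE))) {
          unlink(cd, recursive = TRUE)
        }
      }
    }
  }, add = TRUE)

  archive_url <- sprintf("%s/v2/asset/%s/%s/archive?tag=%s",
                         chosen, p$genome, p$asset, p$tag)
  tryCatch(
    curl::curl_download(archive_url, tmp_tar, quiet = TRUE),
    error = function(e) {
      abort_network(sprintf("download of %s failed: %s",
                            archive_url, conditionMessage(e)))
    }
  )
  got_digest <- sha256_file(tmp_tar)
  if (!identical(got_digest, attrs$archive_digest)) {
    abort_integrity(sprintf(
      "archive digest mismatch for '%s': server advertises %s, downloaded bytes hash to %s",
      format_registry_path(p), attrs$archive_digest, got_digest
    ))
  }

  dir.create(unpack_dir)
  status <- utils::untar(tmp_tar, exdir = unpack_dir)
  if (!identical(status, 0L)) {
    abort_integrity(sprintf("could not unpack archive for '%s'",
                            format_registry_path(p)))
  }
  unpacked_digest <- compute_asset_digest(unpack_dir)
  if (!identical(unpacked_digest, attrs$asset_digest)) {
    abort_integrity(sprintf(
      "asset digest mismatch for '%s' after unpacking: expected %s, got %s",
      format_registry_path(p), attrs$asset_digest, unpacked_digest
    ))
  }

  if (dir.exists(tag_dir)) unlink(tag_dir, recursive = TRUE)
  if (!file.rename(unpack_dir, tag_dir)) {
    refassets_abort(sprintf("could not move pulled asset into '%s'", tag_dir),
                    "refassets_error")
  }
  ok <- TRUE

  sk <- attrs$seek_keys
  sk$dir <- "."
  entry <- list(
    asset_path = paste(p$genome, p$asset, p$tag, sep = "/"),
    seek_keys = sk,
    asset_digest = attrs$asset_digest
  )
  if (BUILD_LOG_FILENAME %in% unlist(attrs$contents)) {
    entry$build_log <- BUILD_LOG_FILENAME
  }
  list(config = set_tag_entry(config, p, entry), entry = entry)
}
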