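# Server side: archive a genome folder into per-asset tarballs plus a
# manifest, and serve archives and metadata over a small read-only HTTP API.
#
# Endpoints (all JSON except the archive bytes; unprefixed forms redirect to
# the /v2 forms):
#   GET /v2/genomes                                   list of genomes
#   GET /v2/assets                                    genome -> [asset, ...]
#   GET /v2/asset/{genome}/{asset}/archive?tag=       gzip tarball bytes
#   GET /v2/asset/{genome}/{asset}/digest?tag=        asset digest (JSON string)
#   GET /v2/asset/{genome}/{asset}/recipe?tag=        canonical recipe text
#   GET /v2/asset/{genome}/{asset}/log?tag=           build log text
#   GET /v2/asset/{genome}/{asset}/attributes?tag=    size, digests, contents, seek keys
#   GET /openapi.json                                 OpenAPI 3.0 description
# The tag query parameter defaults to the asset's default tag. Not-found
# responses are JSON with a machine-readable `level` (genome/asset/tag).

MANIFEST_FILENAME <- "_server_manifest.yaml"

manifest_path_for <- function(config_path) {
  file.path(dirname(config_path), MANIFEST_FILENAME)
}

#' Archive every asset of a genome folder for serving
#'
#' Compresses each (asset, tag) into an individual gzip tarball under
#' `{genome_folder}/_archive/` and writes a server manifest beside the
#' configuration file. The tarball root is the tag directory's contents.
#' Re-running is idempotent: archives whose recorded asset digest still
#' matches are not rewritten.
#'
#' @param config_path Path to the genome configuration file.
#' @return The manifest, an object of class `server_manifest` (list with
#'   `archive_folder` and `entries`), invisibly written to
#'   `_server_manifest.yaml` beside the config.
#' @export
archive_assets <- function(config_path) {
  config <- load_config(config_path)
  listing <- list_local(config)
  if (!length(listing)) {
    refassets_abort("config lists no assets; nothing to archive", "refassets_error")
  }
  archive_folder <- file.path(config$genome_folder, "_archive")
  mpath <- manifest_path_for(config_path)
  old <- if (file.exists(mpath)) load_manifest(mpath) else NULL
  old_by_rp <- list()
  for (e in old$entries) old_by_rp[[e$registry_path]] <- e

  entries <- list()
  for (g in names(config$genomes)) {
    assets <- config$genomes[[g]]$assets
    for (a in names(assets)) {
      for (t in names(assets[[a]]$tags)) {
        te <- assets[[a]]$tags[[t]]
        rp <- sprintf("%s/%s:%s", g, a, t)
        asset_dir <- if (is_abs_path(te$asset_path)) {
          te$asset_path
        } else {
          file.path(config$genome_folder, te$asset_path)
        }
        if (!dir.exists(asset_dir)) {
          abort_missing(sprintf(
            "asset files for '%s' are missing on disk ('%s')", rp, asset_dir
          ), "asset")
        }
        rel_tar <- file.path(g, sprintf("%s__%s.tgz", a, t))
        tar_abs <- file.path(archive_folder, rel_tar)
        prev <- old_by_rp[[rp]]
        if (!is.null(prev) &&
            identical(prev$asset_digest, te$asset_digest) &&
            file.exists(tar_abs)) {
          prev$default_tag <- assets[[a]]$default_tag
          entries[[length(entries) + 1L]] <- prev
          next
        }
        dir.create(dirname(tar_abs), recursive = TRUE, showWarnings = FALSE)
        make_tarball(asset_dir, tar_abs)
        contents <- sort(list.files(asset_dir, recursive = TRUE,
                                    all.files = TRUE, no.. = TRUE),
                         method = "radix")
        recipe_name <- tryCatch(read_build_log(asset_dir)$recipe_name,
                                error = function(e) NULL)
        entry <- list(
          registry_path = rp,
          genome = g,
          asset = a,
          tag = t,
          default_tag = assets[[a]]$default_tag,
          archive_path = rel_tar,
          archive_digest = sha256_file(tar_abs),
          archive_size = as.integer(file.size(tar_abs)),
          contents = as.list(contents),
          asset_digest = te$asset_digest,
          seek_keys = te$seek_keys
        )
        if (!is.null(recipe_name)) entry$recipe_name <- recipe_name
        entries[[length(entries) + 1L]] <- entry
      }
    }
  }
  manifest <- structure(
    list(
      manifest_version = "1.0",
      genome_folder = config$genome_folder,
      archive_folder = archive_folder,
      entries = entries
    ),
    class = "server_manifest"
  )
  write_manifest(manifest, mpath)
  invisible(manifest)
}

make_tarball <- function(src_dir, tar_abs) {
  oldwd <- setwd(src_dir)
  on.exit(setwd(oldwd), add = TRUE)
  files <- list.files(".", all.files = TRUE, no.. = TRUE)
  utils::tar(tar_abs, files = files, compression = "gzip", tar = "internal")
  invisible(tar_abs)
}

#' Write / load a server manifest
#'
#' @param manifest A `server_manifest`.
#' @param path File path (YAML, same dialect as the config file).
#' @return `load_manifest` returns a `server_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(yaml::as.yaml(unclass(manifest), indent = 2L), path, sep = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_missing(sprintf("server manifest '%s' does not exist", path), "manifest")
  }
  structure(yaml::yaml.load_file(path), class = "server_manifest")
}

# --- HTTP plumbing ----------------------------------------------------------

json_response <- function(x, status = 200L) {
  list(
    status = status,
    headers = list("Content-Type" = "application/json"),
    body = jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
  )
}

text_response <- function(txt, status = 200L) {
  list(status = status,
       headers = list("Content-Type" = "text/plain; charset=utf-8"),
       body = txt)
}

not_found <- function(message, level) {
  json_response(list(error = message, level = level), status = 404L)
}

parse_query <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) out[[utils::URLdecode(kv[1])]] <- utils::URLdecode(kv[2])
  }
  out
}

# Locate a manifest entry, distinguishing the failing level.
find_entry <- function(manifest, genome, asset, tag = NULL) {
  entries <- manifest$entries
  g_hits <- Filter(function(e) identical(e$genome, genome), entries)
  if (!length(g_hits)) {
    return(list(error = not_found(sprintf("unknown genome '%s'", genome), "genome")))
  }
  a_hits <- Filter(function(e) identical(e$asset, asset), g_hits)
  if (!length(a_hits)) {
    return(list(error = not_found(
      sprintf("genome '%s' has no asset '%s'", genome, asset), "asset"
    )))
  }
  if (is.null(tag)) tag <- a_hits[[1]]$default_tag
  t_hits <- Filter(function(e) identical(e$tag, tag), a_hits)
  if (!length(t_hits)) {
    return(list(error = not_found(
      sprintf("asset '%s/%s' has no tag '%s'", genome, asset, tag), "tag"
    )))
  }
  list(entry = t_hits[[1]])
}

openapi_document <- function() {
  asset_params <- function(with_tag = TRUE) {
    ps <- list(
      list(name = "genome", `in` = "path", required = TRUE,
           schema = list(type = "string")),
      list(name = "asset", `in` = "path", required = TRUE,
           schema = list(type = "string"))
    )
    if (with_tag) {
      ps[[3]] <- list(name = "tag", `in` = "query", required = FALSE,
                      schema = list(type = "string"))
    }
    ps
  }
  op <- function(summary, params = NULL, content = "application/json") {
    o <- list(summary = summary,
              responses = list(`200` = list(
                description = "OK",
                content = setNames(list(list(schema = list())), content)
              )))
    if (!is.null(params)) o$parameters <- params
    list(get = o)
  }
  list(
    openapi = "3.0.0",
    info = list(title = "refassets archive server",
                description = "Read-only archive and metadata API for reference genome assets",
                version = as.character(utils::packageVersion("refassets"))),
    paths = list(
      "/v2/genomes" = op("List available genomes"),
      "/v2/assets" = op("Map of genome to available assets"),
      "/v2/asset/{genome}/{asset}/archive" = op(
        "Download the asset tarball", asset_params(), "application/octet-stream"),
      "/v2/asset/{genome}/{asset}/digest" = op(
        "Content digest of the asset", asset_params()),
      "/v2/asset/{genome}/{asset}/recipe" = op(
        "Canonical recipe used to build the asset", asset_params(), "text/plain"),
      "/v2/asset/{genome}/{asset}/log" = op(
        "Build log of the asset", asset_params(), "text/plain"),
      "/v2/asset/{genome}/{asset}/attributes" = op(
        "Archive size, digests, contents and seek keys", asset_params())
    )
  )
}

build_app <- function(manifest, config) {
  force(manifest); force(config)
  handle <- function(req) {
    path <- req$PATH_INFO
    if (!identical(req$REQUEST_METHOD, "GET")) {
      return(json_response(list(error = "only GET is supported"), status = 405L))
    }
    query <- parse_query(req$QUERY_STRING)

    if (identical(path, "/openapi.json")) {
      return(json_response(openapi_document()))
    }
    # unprefixed endpoint forms redirect to /v2
    if (grepl("^/(genomes$|assets$|asset/)", path)) {
      loc <- paste0("/v2", path)
      if (!is.null(req$QUERY_STRING) && nzchar(req$QUERY_STRING)) {
        loc <- paste0(loc, sub("^\\?*", "?", req$QUERY_STRING))
      }
      return(list(status = 307L, headers = list(Location = loc), body = ""))
    }

    if (identical(path, "/v2/genomes")) {
      genomes <- unique(vapply(manifest$entries, `[[`, "", "genome"))
      return(json_response(as.list(genomes)))
    }
    if (identical(path, "/v2/assets")) {
      out <- list()
      for (e in manifest$entries) {
        out[[e$genome]] <- unique(c(out[[e$genome]], e$asset))
      }
      return(json_response(lapply(out, as.list)))
    }

    m <- regmatches(path, regexec(
      "^/v2/asset/([^/]+)/([^/]+)/(archive|digest|recipe|log|attributes)$", path
    ))[[1]]
    if (length(m)) {
      found <- find_entry(manifest, m[2], m[3], query$tag)
      if (!is.null(found$error)) return(found$error)
      e <- found$entry
      switch(m[4],
        archive = {
          tar_abs <- file.path(manifest$archive_folder, e$archive_path)
          if (!file.exists(tar_abs)) {
            return(not_found(sprintf("archive for '%s' missing on server",
                                     e$registry_path), "tag"))
          }
          list(status = 200L,
               headers = list("Content-Type" = "application/octet-stream"),
               body = readBin(tar_abs, "raw", n = file.size(tar_abs)))
        },
        digest = json_response(e$asset_digest),
        recipe = {
          if (is.null(e$recipe_name)) {
            return(not_found(sprintf("no recipe recorded for '%s'",
                                     e$registry_path), "tag"))
          }
          text_response(serialize_recipe(get_recipe(e$recipe_name)))
        },
        log = {
          asset_dir <- file.path(manifest$genome_folder, e$genome, e$asset, e$tag)
          log_file <- file.path(asset_dir, BUILD_LOG_FILENAME)
          if (!file.exists(log_file)) {
            return(not_found(sprintf("no build log for '%s'", e$registry_path),
                             "tag"))
          }
          text_response(paste(readLines(log_file, warn = FALSE), collapse = "\n"))
        },
        attributes = json_response(list(
          registry_path = e$registry_path,
          genome = e$genome,
          asset = e$asset,
          tag = e$tag,
          default_tag = e$default_tag,
          archive_digest = e$archive_digest,
          archive_size = e$archive_size,
          contents = e$contents,
          asset_digest = e$asset_digest,
          seek_keys = e$seek_keys
        ))
      )
    } else {
      not_found(sprintf("unknown endpoint '%s'", path), "endpoint")
    }
  }
  list(call = handle)
}

#' Serve archived assets over HTTP
#'
#' Read-only: no request mutates the manifest, the configuration, or the
#' archives. `serve_assets()` starts a background server inside the current
#' process and returns its handle; `run_asset_server()` blocks and serves
#' until interrupted (intended for a dedicated server process).
#'
#' @param config_path Path to the genome configuration file; the manifest
#'   written by [archive_assets()] must exist beside it.
#' @param host Interface to bind.
#' @param port TCP port (0 picks an unused port via [httpuv::randomPort()]).
#' @return For `serve_assets`, a list with `url`, `host`, `port` and the
#'   httpuv `server` handle (stop with [httpuv::stopServer()]).
#' @export
serve_assets <- function(config_path, host = "127.0.0.1", port = 0L) {
  manifest <- load_manifest(manifest_path_for(config_path))
  config <- load_config(config_path)
  if (port == 0L) port <- httpuv::randomPort(host = host)
  server <- httpuv::startServer(host, port, build_app(manifest, config))
  list(url = sprintf("http://%s:%d", host, port),
       host = host, port = port, server = server)
}

#' @rdname serve_assets
#' @export
run_asset_server <- function(config_path, host = "127.0.0.1", port = 8080L) {
  manifest <- load_manifest(manifest_path_for(config_path))
  config <- load_config(config_path)
  httpuv::runServer(host, port, build_app(manifest, config))
}
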