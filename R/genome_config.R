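# The genome configuration file: the YAML document that tracks the genome
# folder, the server URLs, and every local asset with its paths and digest.
# All other modules go through this one.
#
# Schema (canonical key order; two-space indent; UTF-8):
#   config_version: "1.0"
#   genome_folder: /abs/path
#   genome_servers: [url, ...]          # ordered; first has precedence
#   genomes:
#     {genome}:
#       assets:
#         {asset}:
#           default_tag: {tag}
#           tags:
#             {tag}:
#               asset_path: path        # relative to genome_folder, or absolute
#               seek_keys: {key: relpath, ..., dir: .}
#               asset_digest: hex
#               build_log: relpath      # optional
#
# Concurrency contract: every mutation of the on-disk file happens under an
# exclusive advisory lock on a sidecar "<config>.lock" file (see
# with_config_lock()); readers are lock-free. Writes are atomic
# (write-temp-then-rename), so readers never observe a torn file.

CONFIG_VERSION <- "1.0"

#' Construct an in-memory genome configuration
#'
#' @param genome_folder Absolute path under which assets live.
#' @param genome_servers Character vector of server base URLs, in precedence
#'   order.
#' @param genomes Named list of genome entries (usually empty; populated via
#'   [add_asset()] and [build_asset()]).
#' @param config_version Schema version string.
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(genome_folder, genome_servers = character(),
                          genomes = NULL, config_version = CONFIG_VERSION) {
  structure(
    list(
      config_version = config_version,
      genome_folder = genome_folder,
      genome_servers = as.character(genome_servers),
      genomes = if (is.null(genomes)) setNames(list(), character()) else genomes
    ),
    class = "genome_config"
  )
}

#' @export
print.genome_config <- function(x, ...) {
  cat("<genome config> folder:", x$genome_folder, "\n")
  listing <- list_local(x)
  if (!length(listing)) {
    cat("  (no assets)\n")
  } else {
    for (g in names(listing)) {
      cat("  ", g, ": ", paste(listing[[g]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Initialize an empty genome configuration file
#'
#' Creates a configuration file with zero genomes and returns its in-memory
#' form. Refuses to overwrite an existing non-empty file.
#'
#' @param target_path Where to write the configuration file.
#' @param genome_folder Directory under which assets will be stored
#'   (created if absent); recorded as an absolute path.
#' @param servers Character vector of server base URLs.
#' @return The new `genome_config`, invisibly.
#' @export
init_config <- function(target_path,
                        genome_folder = dirname(target_path),
                        servers = character()) {
  if (file.exists(target_path) && file.size(target_path) > 0L) {
    abort_exists(sprintf(
      "config file '%s' already exists and is not empty; refusing to overwrite",
      target_path
    ))
  }
  if (!dir.exists(genome_folder)) {
    dir.create(genome_folder, recursive = TRUE)
  }
  cfg <- genome_config(
    genome_folder = normalizePath(genome_folder, winslash = "/"),
    genome_servers = servers
  )
  write_config(cfg, target_path)
  invisible(cfg)
}

#' Locate the genome configuration file
#'
#' An explicit path (the CLI's `-c` flag) wins; otherwise the `REFGENIE`
#' environment variable is consulted.
#'
#' @param explicit Optional explicit file path.
#' @param environment Named character vector of environment variables
#'   (injectable for testing; defaults to the process environment).
#' @return The resolved file path.
#' @export
resolve_config_location <- function(explicit = NULL,
                                    environment = Sys.getenv()) {
  if (!is.null(explicit) && nzchar(explicit)) {
    return(explicit)
  }
  env_val <- if ("REFGENIE" %in% names(environment)) environment[["REFGENIE"]] else ""
  if (nzchar(env_val)) {
    return(env_val)
  }
  abort_usage(paste(
    "no genome configuration file: pass one explicitly (-c/config argument)",
    "or set the REFGENIE environment variable"
  ))
}

config_as_list <- function(config) {
  genomes <- config$genomes
  glist <- lapply(genomes, function(g) {
    list(assets = lapply(g$assets, function(a) {
      list(
        default_tag = a$default_tag,
        tags = lapply(a$tags, function(t) {
          out <- list(
            asset_path = t$asset_path,
            seek_keys = t$seek_keys,
            asset_digest = t$asset_digest
          )
          if (!is.null(t$build_log)) out$build_log <- t$build_log
          out
        })
      )
    }))
  })
  list(
    config_version = config$config_version,
    genome_folder = config$genome_folder,
    genome_servers = as.list(config$genome_servers),
    genomes = if (length(glist)) glist else setNames(list(), character())
  )
}

#' Write a genome configuration file
#'
#' Canonical rendering (fixed key order, two-space indent), written
#' atomically: the YAML goes to a temporary file in the same directory which
#' is then renamed into place.
#'
#' @param config A `genome_config`.
#' @param path Target file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "genome_config"))
  txt <- yaml::as.yaml(config_as_list(config), indent = 2L)
  tmp <- tempfile(pattern = ".config_", tmpdir = dirname(path))
  writeLines(txt, tmp, sep = "")
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    refassets_abort(sprintf("cannot write config file '%s'", path), "refassets_error")
  }
  invisible(path)
}

validate_config_list <- function(x, path) {
  if (!is.list(x)) {
    abort_schema(sprintf("config file '%s' is not a YAML mapping", path))
  }
  required <- c("config_version", "genome_folder", "genomes")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort_schema(sprintf(
      "config file '%s' is missing required keys: %s",
      path, paste(missing, collapse = ", ")
    ))
  }
  major <- sub("\\..*$", "", as.character(x$config_version))
  if (!identical(major, sub("\\..*$", "", CONFIG_VERSION))) {
    abort_schema(sprintf(
      "unsupported config_version '%s' in '%s' (this build reads major version %s)",
      x$config_version, path, sub("\\..*$", "", CONFIG_VERSION)
    ))
  }
  bad <- character()
  for (g in names(x$genomes)) {
    assets <- x$genomes[[g]]$assets
    if (is.null(assets)) {
      bad <- c(bad, sprintf("genomes.%s.assets", g))
      next
    }
    for (a in names(assets)) {
      entry <- assets[[a]]
      if (is.null(entry$default_tag) || is.null(entry$tags)) {
        bad <- c(bad, sprintf("genomes.%s.assets.%s", g, a))
        next
      }
      for (t in names(entry$tags)) {
        te <- entry$tags[[t]]
        need <- c("asset_path", "seek_keys", "asset_digest")
        miss <- need[!need %in% names(te)]
        if (length(miss)) {
          bad <- c(bad, sprintf("genomes.%s.assets.%s.tags.%s.{%s}",
                                g, a, t, paste(miss, collapse = ",")))
        }
      }
      if (!entry$default_tag %in% names(entry$tags)) {
        bad <- c(bad, sprintf("genomes.%s.assets.%s.default_tag", g, a))
      }
    }
  }
  if (length(bad)) {
    abort_schema(sprintf(
      "config file '%s' has malformed entries at: %s",
      path, paste(bad, collapse = "; ")
    ))
  }
  invisible(TRUE)
}

#' Load a genome configuration file
#'
#' @param path Path to the configuration file.
#' @return A `genome_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    refassets_abort(sprintf("config file '%s' does not exist", path),
                    "refassets_missing_error", level = "config")
  }
  x <- tryCatch(
    yaml::yaml.load_file(path),
    error = function(e) {
      abort_schema(sprintf("config file '%s' is not valid YAML: %s",
                           path, conditionMessage(e)))
    }
  )
  validate_config_list(x, path)
  genome_config(
    genome_folder = x$genome_folder,
    genome_servers = unlist(x$genome_servers) %||% character(),
    genomes = if (length(x$genomes)) x$genomes else NULL,
    config_version = as.character(x$config_version)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a config mutation under the modification lock
#'
#' Acquires an exclusive advisory lock on the sidecar `<path>.lock` file,
#' loads the config, applies `fn` to it, writes the result back atomically,
#' and releases the lock. This is the only safe way to mutate a shared
#' on-disk configuration (the CLI and the archive server operate on the same
#' file).
#'
#' @param path Config file path.
#' @param fn Function `genome_config -> genome_config`.
#' @param timeout Lock wait in milliseconds.
#' @return The updated `genome_config`, invisibly.
#' @export
with_config_lock <- function(path, fn, timeout = 30000) {
  lck <- filelock::lock(paste0(path, ".lock"), timeout = timeout)
  if (is.null(lck)) {
    refassets_abort(sprintf("could not lock config file '%s'", path),
                    "refassets_error")
  }
  on.exit(filelock::unlock(lck), add = TRUE)
  cfg <- load_config(path)
  cfg <- fn(cfg)
  write_config(cfg, path)
  invisible(cfg)
}

# --- lookup helpers ---------------------------------------------------------

get_tag_entry <- function(config, p) {
  g <- config$genomes[[p$genome]]
  if (is.null(g)) {
    abort_missing(sprintf("genome '%s' not found in config", p$genome), "genome")
  }
  a <- g$assets[[p$asset]]
  if (is.null(a)) {
    abort_missing(sprintf("genome '%s' has no asset '%s'", p$genome, p$asset), "asset")
  }
  t <- a$tags[[p$tag]]
  if (is.null(t)) {
    abort_missing(sprintf("asset '%s/%s' has no tag '%s'", p$genome, p$asset, p$tag), "tag")
  }
  t
}

is_abs_path <- function(p) startsWith(p, "/")

# TRUE if `child` (an existing path) lies inside directory `parent`.
path_is_within <- function(child, parent) {
  child <- normalizePath(child, winslash = "/", mustWork = FALSE)
  parent <- normalizePath(parent, winslash = "/", mustWork = FALSE)
  identical(child, parent) || startsWith(child, paste0(parent, "/"))
}

#' List local genomes and assets
#'
#' @param config A `genome_config`.
#' @return Named list: genome -> character vector of `"asset:tag"` entries,
#'   one per tag of every asset.
#' @export
list_local <- function(config) {
  out <- list()
  for (g in names(config$genomes)) {
    entries <- character()
    assets <- config$genomes[[g]]$assets
    for (a in names(assets)) {
      entries <- c(entries, paste0(a, ":", names(assets[[a]]$tags)))
    }
    out[[g]] <- entries
  }
  out
}

#' Register an already-built local asset
#'
#' Records `local_dir` as the asset directory for the given registry path and
#' computes its content digest. Directories located outside the genome folder
#' are recorded by absolute path and never copied; directories inside it are
#' recorded relative to the genome folder.
#'
#' @param config A `genome_config`.
#' @param path Registry path (string or parsed).
#' @param local_dir Existing, non-empty directory holding the asset files.
#' @param seek_keys Named list of seek key -> path relative to `local_dir`.
#'   The reserved key `dir` (the directory itself) is added automatically.
#' @param build_log Optional path, relative to `local_dir`, of a build log.
#' @param force Overwrite an existing tag entry.
#' @return The updated `genome_config`.
#' @export
add_asset <- function(config, path, local_dir, seek_keys = list(),
                      build_log = NULL, force = FALSE) {
  p <- as_registry_path(path)
  if (!dir.exists(local_dir)) {
    abort_missing(sprintf("asset directory '%s' does not exist", local_dir), "asset")
  }
  if (!length(list.files(local_dir, all.files = TRUE, no.. = TRUE))) {
    refassets_abort(sprintf("asset directory '%s' is empty", local_dir),
                    "refassets_error")
  }
  existing <- config$genomes[[p$genome]]$assets[[p$asset]]$tags[[p$tag]]
  if (!is.null(existing) && !force) {
    abort_exists(sprintf(
      "asset '%s/%s:%s' already exists; use force to overwrite",
      p$genome, p$asset, p$tag
    ))
  }
  local_dir <- normalizePath(local_dir, winslash = "/")
  asset_path <- if (path_is_within(local_dir, config$genome_folder)) {
    substring(local_dir, nchar(config$genome_folder) + 2L)
  } else {
    local_dir
  }
  sk <- as.list(seek_keys)
  sk$dir <- "."
  entry <- list(
    asset_path = asset_path,
    seek_keys = sk,
    asset_digest = compute_asset_digest(local_dir)
  )
  if (!is.null(build_log)) entry$build_log <- build_log
  set_tag_entry(config, p, entry)
}

# Insert/replace a tag entry, creating genome/asset levels as needed.
set_tag_entry <- function(config, p, entry) {
  if (is.null(config$genomes[[p$genome]])) {
    config$genomes[[p$genome]] <- list(assets = setNames(list(), character()))
  }
  if (is.null(config$genomes[[p$genome]]$assets[[p$asset]])) {
    config$genomes[[p$genome]]$assets[[p$asset]] <-
      list(default_tag = p$tag, tags = setNames(list(), character()))
  }
  config$genomes[[p$genome]]$assets[[p$asset]]$tags[[p$tag]] <- entry
  config
}

#' Remove a local asset
#'
#' Deletes the tag's entry from the configuration. Files are deleted from
#' disk only when the asset directory lies inside the genome folder; assets
#' registered in place elsewhere are deregistered only. Removing the last
#' tag removes the asset (and, if empty, the genome) entry entirely.
#'
#' @param config A `genome_config`.
#' @param path Registry path (string or parsed).
#' @return The updated `genome_config`.
#' @export
remove_asset <- function(config, path) {
  p <- as_registry_path(path)
  entry <- get_tag_entry(config, p)
  if (!is_abs_path(entry$asset_path)) {
    target <- file.path(config$genome_folder, entry$asset_path)
    unlink(target, recursive = TRUE)
    # prune now-empty parent directories up to the genome folder
    parent <- dirname(target)
    while (path_is_within(parent, config$genome_folder) &&
           !identical(normalizePath(parent, winslash = "/", mustWork = FALSE),
                      config$genome_folder) &&
           dir.exists(parent) &&
           !length(list.files(parent, all.files = TRUE, no.. = TRUE))) {
      unlink(parent, recursive = TRUE)
      parent <- dirname(parent)
    }
  }
  asset <- config$genomes[[p$genome]]$assets[[p$asset]]
  asset$tags[[p$tag]] <- NULL
  if (!length(asset$tags)) {
    config$genomes[[p$genome]]$assets[[p$asset]] <- NULL
  } else {
    if (identical(asset$default_tag, p$tag)) {
      asset$default_tag <- sort(names(asset$tags), method = "radix")[1L]
    }
    config$genomes[[p$genome]]$assets[[p$asset]] <- asset
  }
  if (!length(config$genomes[[p$genome]]$assets)) {
    config$genomes[[p$genome]] <- NULL
  }
  if (!length(config$genomes)) {
    config$genomes <- setNames(list(), character())
  }
  config
}

#' Tag an asset with an additional name
#'
#' Creates an alias: the new tag references the same asset directory, seek
#' keys and digest; no files are copied. The default tag is not re-pointed.
#'
#' @param config A `genome_config`.
#' @param path Registry path of the existing tag.
#' @param new_tag Token for the new tag.
#' @param force Overwrite an existing tag of that name.
#' @return The updated `genome_config`.
#' @export
tag_asset <- function(config, path, new_tag, force = FALSE) {
  p <- as_registry_path(path)
  if (!grepl(sprintf("^%s$", REGISTRY_TOKEN_RE), new_tag)) {
    abort_parse(sprintf("invalid tag name '%s'", new_tag))
  }
  entry <- get_tag_entry(config, p)
  if (identical(new_tag, p$tag)) {
    abort_usage(sprintf("new tag '%s' is the same as the source tag", new_tag))
  }
  tags <- config$genomes[[p$genome]]$assets[[p$asset]]$tags
  if (new_tag %in% names(tags) && !force) {
    abort_exists(sprintf(
      "tag '%s' already exists on '%s/%s'; use force to overwrite",
      new_tag, p$genome, p$asset
    ))
  }
  config$genomes[[p$genome]]$assets[[p$asset]]$tags[[new_tag]] <- entry
  config
}

# The default seek key of an asset: the key a plain `seek genome/asset`
# resolves. Defined by the recipe of the same name when one exists; for
# assets registered without a recipe, a key matching the asset name wins,
# then the only non-dir key, then `dir`.
default_seek_key_for <- function(asset_name, seek_keys) {
  rec <- tryCatch(get_recipe(asset_name), error = function(e) NULL)
  if (!is.null(rec) && rec$default_seek_key %in% names(seek_keys)) {
    return(rec$default_seek_key)
  }
  if (asset_name %in% names(seek_keys)) {
    return(asset_name)
  }
  non_dir <- setdiff(names(seek_keys), "dir")
  if (length(non_dir) == 1L) {
    return(non_dir)
  }
  "dir"
}

#' Resolve a registry path to a file path
#'
#' A pure lookup: returns the absolute path recorded in the configuration,
#' never touching the filesystem. Without a seek key the asset's default
#' seek key is resolved (for a `fasta` asset, the sequence file); the
#' reserved key `dir` resolves the asset directory itself.
#'
#' @param config A `genome_config`.
#' @param path Registry path (string or parsed), e.g.
#'   `"hg38/fasta.chrom_sizes:default"`.
#' @return Absolute file path as a bare string.
#' @export
seek_asset <- function(config, path) {
  p <- as_registry_path(path)
  entry <- get_tag_entry(config, p)
  key <- p$seek_key %||% default_seek_key_for(p$asset, entry$seek_keys)
  if (!key %in% names(entry$seek_keys)) {
    abort_missing(sprintf(
      "asset '%s/%s:%s' has no seek key '%s' (available: %s)",
      p$genome, p$asset, p$tag, key,
      paste(names(entry$seek_keys), collapse = ", ")
    ), "seek_key")
  }
  base <- if (is_abs_path(entry$asset_path)) {
    entry$asset_path
  } else {
    file.path(config$genome_folder, entry$asset_path)
  }
  rel <- entry$seek_keys[[key]]
  if (identical(rel, ".")) base else file.path(base, rel)
}
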