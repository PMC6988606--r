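# Recipe framework and the build operation: materialize an asset from
# arbitrary user inputs under the standard {genome_folder}/{genome}/{asset}/
# {tag}/ layout, then register it in the configuration.
#
# Exactly one recipe (`fasta`) is fully internal -- its procedure is
# implemented here and runs in tests. The aligner-index recipes
# (bowtie2_index, hisat2_index, bwa_index) are declarative command
# templates: they describe the external build faithfully but are never
# executed unless the caller explicitly allows execution.

TEMPLATE_BUILTINS <- c("genome", "asset", "tag", "output_dir")

recipe_registry <- new.env(parent = emptyenv())

template_placeholders <- function(templates) {
  hits <- regmatches(templates, gregexpr("\\{[A-Za-z0-9_]+\\}", templates))
  unique(gsub("[{}]", "", unlist(hits)))
}

#' Construct (and validate) a recipe
#'
#' Normally recipes come from the packaged manifest
#' (`inst/extdata/recipes.yaml`); this constructor is exported so that new
#' declarative recipes can be registered programmatically.
#'
#' @param name Recipe name (equals the asset name it builds).
#' @param version Recipe version string, recorded in build logs.
#' @param description Human-readable description.
#' @param required_files List of `list(name=, description=)` input files.
#' @param required_assets Character vector of prerequisite asset names.
#' @param required_params List of `list(name=, default=)` parameters.
#' @param outputs Named list: seek key -> output path template (relative to
#'   the asset directory; placeholders allowed).
#' @param default_seek_key The seek key a plain `seek` resolves; must be one
#'   of `names(outputs)`.
#' @param procedure Either `list(kind = "internal", entry = <fn name>)` or
#'   `list(kind = "command_template", command = <template>)`.
#' @return A `recipe` object.
#' @export
recipe <- function(name, version, description, required_files = list(),
                   required_assets = character(), required_params = list(),
                   outputs, default_seek_key, procedure) {
  if (!default_seek_key %in% names(outputs)) {
    refassets_abort(sprintf(
      "recipe '%s': default_seek_key '%s' is not among its outputs (%s)",
      name, default_seek_key, paste(names(outputs), collapse = ", ")
    ), "refassets_error")
  }
  declared <- c(
    TEMPLATE_BUILTINS,
    vapply(required_files, `[[`, "", "name"),
    as.character(required_assets),
    vapply(required_params, `[[`, "", "name")
  )
  templates <- unlist(outputs)
  if (identical(procedure$kind, "command_template")) {
    templates <- c(templates, procedure$command)
  }
  undeclared <- setdiff(template_placeholders(templates), declared)
  if (length(undeclared)) {
    refassets_abort(sprintf(
      "recipe '%s' references undeclared placeholder(s): %s",
      name, paste(undeclared, collapse = ", ")
    ), "refassets_error")
  }
  structure(
    list(
      name = name,
      version = version,
      description = description,
      required_files = required_files,
      required_assets = as.character(required_assets),
      required_params = required_params,
      outputs = outputs,
      default_seek_key = default_seek_key,
      procedure = procedure
    ),
    class = "recipe"
  )
}

load_recipe_manifest <- function() {
  path <- system.file("extdata", "recipes.yaml", package = "refassets")
  man <- yaml::yaml.load_file(path)
  for (nm in names(man$recipes)) {
    r <- man$recipes[[nm]]
    recipe_registry[[nm]] <- recipe(
      name = nm,
      version = r$version,
      description = r$description,
      required_files = r$required_files %||% list(),
      required_assets = unlist(r$required_assets) %||% character(),
      required_params = r$required_params %||% list(),
      outputs = r$outputs,
      default_seek_key = r$default_seek_key,
      procedure = r$procedure
    )
  }
}

ensure_recipes_loaded <- function() {
  if (!length(ls(recipe_registry))) load_recipe_manifest()
}

#' Look up a recipe by name
#'
#' @param name Recipe name.
#' @return A `recipe` object.
#' @export
get_recipe <- function(name) {
  ensure_recipes_loaded()
  r <- recipe_registry[[name]]
  if (is.null(r)) {
    abort_missing(sprintf(
      "no recipe '%s' (known recipes: %s)",
      name, paste(sort(ls(recipe_registry)), collapse = ", ")
    ), "recipe")
  }
  r
}

requirements_summary <- function(r) {
  parts <- character()
  if (length(r$required_files)) {
    parts <- c(parts, paste0(
      "files: ", paste(vapply(r$required_files, `[[`, "", "name"), collapse = ", ")
    ))
  }
  if (length(r$required_assets)) {
    parts <- c(parts, paste0("assets: ", paste(r$required_assets, collapse = ", ")))
  }
  if (length(r$required_params)) {
    parts <- c(parts, paste0(
      "params: ",
      paste(vapply(r$required_params, function(p) {
        paste0(p$name, "=", p$default)
      }, ""), collapse = ", ")
    ))
  }
  if (!length(parts)) "none" else paste(parts, collapse = "; ")
}

#' List available build recipes
#'
#' @return A data frame with columns `name`, `kind` (internal or
#'   command_template) and `requirements` (summary text).
#' @export
list_recipes <- function() {
  ensure_recipes_loaded()
  nms <- sort(ls(recipe_registry), method = "radix")
  data.frame(
    name = nms,
    kind = vapply(nms, function(n) recipe_registry[[n]]$procedure$kind, ""),
    requirements = vapply(nms, function(n) {
      requirements_summary(recipe_registry[[n]])
    }, ""),
    row.names = NULL
  )
}

#' Describe what building an asset requires
#'
#' @param recipe_name Name of the recipe.
#' @return A list with elements `files` (character vector of required input
#'   file names), `assets` (prerequisite asset names) and `params` (named
#'   character vector of parameter defaults).
#' @export
describe_requirements <- function(recipe_name) {
  r <- get_recipe(recipe_name)
  params <- vapply(r$required_params, `[[`, "", "default")
  names(params) <- vapply(r$required_params, `[[`, "", "name")
  list(
    files = vapply(r$required_files, `[[`, "", "name"),
    assets = r$required_assets,
    params = params
  )
}

#' Construct a build request
#'
#' @param registry_path Registry path (string or parsed) of the asset to
#'   build; a seek-key suffix is not allowed here.
#' @param files Named list/vector: required input name -> file path.
#' @param params Named list/vector of parameter overrides.
#' @return A `build_request` object.
#' @export
build_request <- function(registry_path, files = list(), params = list()) {
  p <- as_registry_path(registry_path)
  if (!is.null(p$seek_key)) {
    abort_usage(sprintf(
      "registry path for build must not carry a seek key (got '%s')",
      format_registry_path(p)
    ))
  }
  structure(
    list(registry_path = p, files = as.list(files), params = as.list(params)),
    class = "build_request"
  )
}

substitute_template <- function(template, values) {
  for (n in names(values)) {
    template <- gsub(paste0("{", n, "}"), values[[n]], template, fixed = TRUE)
  }
  left <- template_placeholders(template)
  if (length(left)) {
    refassets_abort(sprintf(
      "unresolved placeholder(s) %s in template '%s'",
      paste(left, collapse = ", "), template
    ), "refassets_error")
  }
  template
}

# Parameter values after filling recipe defaults; missing defaults are an
# error naming the parameter.
resolve_params <- function(r, params) {
  out <- list()
  for (p in r$required_params) {
    out[[p$name]] <- params[[p$name]] %||% p$default
    if (is.null(out[[p$name]])) {
      abort_build(sprintf("missing required parameter '%s' (recipe '%s')",
                          p$name, r$name))
    }
  }
  out
}

#' Render the shell command of a declarative recipe
#'
#' Substitutes every placeholder of a command-template recipe with the
#' request's inputs and the resolved asset/output paths. Purely textual;
#' nothing is executed.
#'
#' @param recipe A command-template `recipe`.
#' @param request A `build_request`.
#' @param resolved_paths Named list: prerequisite asset name -> local path,
#'   plus `output_dir`.
#' @return The command as a single string.
#' @export
render_command <- function(recipe, request, resolved_paths) {
  stopifnot(inherits(recipe, "recipe"), inherits(request, "build_request"))
  if (!identical(recipe$procedure$kind, "command_template")) {
    abort_usage(sprintf("recipe '%s' has no command template", recipe$name))
  }
  p <- request$registry_path
  values <- c(
    list(genome = p$genome, asset = p$asset, tag = p$tag),
    request$files,
    resolve_params(recipe, request$params),
    resolved_paths
  )
  substitute_template(recipe$procedure$command, values)
}

#' Build the fasta asset: sequences, FAI index, chromosome sizes
#'
#' Reads a FASTA file (plain or gzip-compressed) and writes three outputs
#' into `output_dir`: the uncompressed sequences (line structure preserved,
#' LF line endings), a 5-column FAI index (name, sequence length in bases,
#' byte offset of the first base, bases per line, bytes per line), and a
#' two-column `name<TAB>length` chromosome-sizes table in input order.
#'
#' @param input_fasta Path to the input FASTA.
#' @param output_dir Existing directory to write into.
#' @param name Basename stem for the outputs (`<name>.fa`, `<name>.fa.fai`,
#'   `<name>.chrom.sizes`); defaults to the input filename stem.
#' @return Named character vector of output paths with names `fasta`, `fai`
#'   and `chrom_sizes`.
#' @export
build_fasta <- function(input_fasta, output_dir, name = NULL) {
  if (!file.exists(input_fasta)) {
    abort_build(sprintf("input fasta '%s' does not exist", input_fasta))
  }
  if (is.null(name)) {
    name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(input_fasta))
  }
  con <- if (is_gzipped(input_fasta)) {
    gzfile(input_fasta, "rt")
  } else {
    file(input_fasta, "rt")
  }
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  if (!length(lines)) {
    abort_build(sprintf("input fasta '%s' is empty", input_fasta))
  }
  if (!startsWith(lines[1L], ">")) {
    abort_build(sprintf("input '%s' is not FASTA: first line is not a header",
                        input_fasta))
  }

  fasta_out <- file.path(output_dir, paste0(name, ".fa"))
  fai_out <- paste0(fasta_out, ".fai")
  sizes_out <- file.path(output_dir, paste0(name, ".chrom.sizes"))
  writeLines(lines, fasta_out)  # uncompressed copy, LF endings

  header_idx <- which(startsWith(lines, ">"))
  nbytes <- nchar(lines, type = "bytes")
  seq_names <- vapply(lines[header_idx], function(h) {
    strsplit(sub("^>", "", h), "[ \t]")[[1]][1]
  }, "", USE.NAMES = FALSE)
  if (anyNA(seq_names) || !all(nzchar(seq_names))) {
    abort_build(sprintf("input fasta '%s' has a header with no sequence name",
                        input_fasta))
  }
  dup <- seq_names[duplicated(seq_names)]
  if (length(dup)) {
    abort_build(sprintf("duplicate sequence name(s) in '%s': %s",
                        input_fasta, paste(unique(dup), collapse = ", ")))
  }

  # Byte offset of each line in the uncompressed output (LF = 1 byte).
  offsets <- c(0, cumsum(nbytes + 1L))
  block_end <- c(header_idx[-1L] - 1L, length(lines))
  fai_rows <- character(length(header_idx))
  sizes_rows <- character(length(header_idx))
  for (i in seq_along(header_idx)) {
    first <- header_idx[i] + 1L
    last <- block_end[i]
    if (first > last) {
      abort_build(sprintf("sequence '%s' in '%s' has no sequence lines",
                          seq_names[i], input_fasta))
    }
    widths <- nbytes[first:last]
    linebases <- widths[1L]
    if (length(widths) > 1L) {
      body <- widths[-length(widths)]
      if (any(body != linebases) || widths[length(widths)] > linebases) {
        abort_build(sprintf(
          "sequence '%s' in '%s' has ragged line lengths; FAI cannot represent it",
          seq_names[i], input_fasta
        ))
      }
    }
    total <- sum(widths)
    fai_rows[i] <- paste(seq_names[i], total, offsets[first],
                         linebases, linebases + 1L, sep = "\t")
    sizes_rows[i] <- paste(seq_names[i], total, sep = "\t")
  }
  writeLines(fai_rows, fai_out)
  writeLines(sizes_rows, sizes_out)
  c(fasta = fasta_out, fai = fai_out, chrom_sizes = sizes_out)
}

is_gzipped <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Build an asset and register it
#'
#' Checks the recipe's requirements, builds into a temporary sibling
#' directory, computes the asset digest, writes the build log, renames the
#' directory into `{genome_folder}/{genome}/{asset}/{tag}/` on success, and
#' returns the updated configuration. On any failure the partial build
#' directory is removed and the configuration is untouched.
#'
#' @param config A `genome_config`.
#' @param request A `build_request` (or a registry path string, for
#'   convenience, combined with `files`/`params`).
#' @param files,params Used only when `request` is given as a string.
#' @param force Rebuild over an existing tag.
#' @param allow_execution Permit running command-template recipes through the
#'   shell. Off by default: such recipes then fail with an explanatory error.
#' @return A list with elements `config` (updated `genome_config`) and
#'   `entry` (the new tag entry: asset_path, seek_keys, asset_digest,
#'   build_log).
#' @export
build_asset <- function(config, request, files = list(), params = list(),
                        force = FALSE, allow_execution = FALSE) {
  if (!inherits(request, "build_request")) {
    request <- build_request(request, files = files, params = params)
  }
  p <- request$registry_path
  r <- get_recipe(p$asset)

  # -- requirements, checked before any write --
  for (f in r$required_files) {
    got <- request$files[[f$name]]
    if (is.null(got)) {
      abort_build(sprintf(
        "missing required input file '%s' for recipe '%s' (pass files = list(%s = <path>))",
        f$name, r$name, f$name
      ))
    }
    if (!file.exists(got)) {
      abort_build(sprintf("required input file '%s' ('%s') does not exist",
                          f$name, got))
    }
  }
  dep_paths <- list()
  for (dep in r$required_assets) {
    dep_paths[[dep]] <- tryCatch(
      seek_asset(config, sprintf("%s/%s", p$genome, dep)),
      refassets_missing_error = function(e) {
        abort_build(sprintf(
          "recipe '%s' requires asset '%s/%s'; build or pull it first",
          r$name, p$genome, dep
        ))
      }
    )
  }
  params_resolved <- resolve_params(r, request$params)
  existing <- config$genomes[[p$genome]]$assets[[p$asset]]$tags[[p$tag]]
  if (!is.null(existing) && !force) {
    abort_exists(sprintf(
      "asset '%s/%s:%s' already exists; use force to rebuild",
      p$genome, p$asset, p$tag
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
  tmp_dir <- tempfile(pattern = sprintf(".tmp_%s_", p$tag), tmpdir = parent)
  dir.create(tmp_dir)
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(tmp_dir, recursive = TRUE)
      # roll back directory levels this build created
      for (cd in rev(created_dirs)) {
        if (dir.exists(cd) &&
            !length(list.files(cd, all.files = TRUE, no.. = TRUE))) {
          unlink(cd, recursive = TRUE)
        }
      }
    }
  }, add = TRUE)

  started <- utc_now()
  values <- c(list(genome = p$genome, asset = p$asset, tag = p$tag,
                   output_dir = tmp_dir),
              dep_paths, params_resolved)
  expected <- vapply(r$outputs, substitute_template, "", values = values)

  if (identical(r$procedure$kind, "internal")) {
    entry_fn <- switch(r$procedure$entry,
      build_fasta = function() build_fasta(request$files$fasta, tmp_dir,
                                           name = p$genome),
      abort_build(sprintf("unknown internal procedure '%s'", r$procedure$entry))
    )
    entry_fn()
    produced <- sort(list.files(tmp_dir, recursive = TRUE, all.files = TRUE,
                                no.. = TRUE))
    if (!identical(produced, sort(unname(expected)))) {
      abort_build(sprintf(
        "recipe '%s' produced {%s} but declares outputs {%s}",
        r$name, paste(produced, collapse = ", "),
        paste(expected, collapse = ", ")
      ))
    }
  } else {
    cmd <- render_command(r, request, c(dep_paths, list(output_dir = tmp_dir)))
    if (!allow_execution) {
      abort_build(sprintf(
        "recipe '%s' requires external execution, not supported in this environment (command would be: %s); set allow_execution = TRUE to run it",
        r$name, cmd
      ))
    }
    status <- system(cmd)
    if (!identical(status, 0L)) {
      abort_build(sprintf("command failed (exit %d): %s", status, cmd))
    }
  }

  adigest <- compute_asset_digest(tmp_dir)
  inputs <- lapply(names(request$files), function(n) {
    list(name = n, path = as.character(request$files[[n]]),
         digest = sha256_file(request$files[[n]]))
  })
  log <- build_log(
    registry_path = format_registry_path(p),
    recipe_name = r$name,
    recipe_version = r$version,
    inputs = inputs,
    software_versions = list(
      refassets = as.character(utils::packageVersion("refassets")),
      R = R.version.string
    ),
    started = started,
    finished = utc_now(),
    asset_digest = adigest
  )
  write_build_log(tmp_dir, log)

  if (dir.exists(tag_dir)) unlink(tag_dir, recursive = TRUE)
  if (!file.rename(tmp_dir, tag_dir)) {
    abort_build(sprintf("could not move build directory into place at '%s'",
                        tag_dir))
  }
  ok <- TRUE

  seek_keys <- as.list(expected)
  seek_keys$dir <- "."
  entry <- list(
    asset_path = paste(p$genome, p$asset, p$tag, sep = "/"),
    seek_keys = seek_keys,
    asset_digest = adigest,
    build_log = BUILD_LOG_FILENAME
  )
  list(config = set_tag_entry(config, p, entry), entry = entry)
}
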