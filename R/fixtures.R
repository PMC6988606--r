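# Seeded synthetic data and an in-process test harness: everything the test
# suite needs is generated from a seed, with no downloads.
#
# Random source: R's default Mersenne-Twister generator, seeded locally (the
# caller's RNG state is saved and restored), so fixture bytes depend only on
# the seed and parameters.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Generate a synthetic FASTA text
#'
#' Deterministic for a fixed seed: record names are `chr1..chrN`, sequence
#' lengths are drawn uniformly from `length_range`, and bases are drawn from
#' the alphabet ACGTN (N at 2%, mimicking occasional ambiguous calls).
#'
#' @param n_records Number of sequence records (>= 1).
#' @param length_range Two-element integer vector `c(min, max)` of sequence
#'   lengths, `min >= 1`.
#' @param line_width Bases per line in the output.
#' @param seed Integer seed.
#' @return A single string of FASTA text (with trailing newline).
#' @export
generate_fasta <- function(n_records, length_range, line_width = 60L, seed = 1L) {
  if (n_records < 1L) {
    abort_usage("n_records must be >= 1")
  }
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[2] < length_range[1]) {
    abort_usage("length_range must be c(min, max) with 1 <= min <= max")
  }
  if (line_width < 1L) {
    abort_usage("line_width must be >= 1")
  }
  with_local_seed(seed, {
    chunks <- character(n_records)
    for (i in seq_len(n_records)) {
      len <- sample(seq.int(length_range[1], length_range[2]), 1L)
      bases <- sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                      prob = c(0.245, 0.245, 0.245, 0.245, 0.02))
      seq <- paste(bases, collapse = "")
      starts <- seq.int(1L, len, by = line_width)
      lines <- substring(seq, starts, pmin(starts + line_width - 1L, len))
      chunks[i] <- paste0(">chr", i, "\n", paste(lines, collapse = "\n"), "\n")
    }
    paste(chunks, collapse = "")
  })
}

#' Write FASTA text to a file, optionally gzip-compressed
#'
#' @param text FASTA text (e.g. from [generate_fasta()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(text, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeBin(charToRaw(text), con)
  close(con)
  invisible(path)
}

#' Create a populated genome configuration for testing
#'
#' Initializes a config under `tmp_root`, generates one synthetic genome
#' sequence per genome (`genome1..genomeN`), builds its `fasta` asset, and
#' registers `n_assets - 1` additional plain-file assets (`ann1`, `ann2`,
#' ...) per genome. Everything derives from `seed`.
#'
#' @param tmp_root Directory to create the config and genome folder in.
#' @param n_genomes Number of genomes.
#' @param n_assets Assets per genome (the first is always `fasta`).
#' @param seed Integer seed.
#' @param seq_length Range of sequence lengths per record.
#' @param n_records Records per genome.
#' @return List with `config_path`, `config` (the in-memory state) and
#'   `expected` (the ground-truth [list_local()] listing).
#' @export
make_populated_config <- function(tmp_root, n_genomes = 2L, n_assets = 1L,
                                  seed = 1L, seq_length = c(500L, 2000L),
                                  n_records = 3L) {
  config_path <- file.path(tmp_root, "genome_config.yaml")
  genome_folder <- file.path(tmp_root, "genomes")
  cfg <- init_config(config_path, genome_folder = genome_folder)
  expected <- list()
  for (gi in seq_len(n_genomes)) {
    genome <- paste0("genome", gi)
    fa <- generate_fasta(n_records, seq_length, line_width = 60L,
                         seed = seed * 1000L + gi)
    fa_path <- file.path(tmp_root, paste0(genome, ".fa.gz"))
    write_fasta(fa, fa_path)
    cfg <- build_asset(cfg, sprintf("%s/fasta", genome),
                       files = list(fasta = fa_path))$config
    entries <- "fasta:default"
    if (n_assets > 1L) {
      for (ai in seq_len(n_assets - 1L)) {
        aname <- paste0("ann", ai)
        adir <- file.path(cfg$genome_folder, genome, aname, "default")
        dir.create(adir, recursive = TRUE)
        with_local_seed(seed * 10000L + gi * 100L + ai, {
          writeLines(sprintf("feature_%d\t%d", 1:5, sample.int(1e6, 5L)),
                     file.path(adir, paste0(aname, ".tsv")))
        })
        cfg <- add_asset(cfg, sprintf("%s/%s", genome, aname), adir,
                         seek_keys = setNames(list(paste0(aname, ".tsv")), aname))
        entries <- c(entries, paste0(aname, ":default"))
      }
    }
    expected[[genome]] <- entries
  }
  write_config(cfg, config_path)
  list(config_path = config_path, config = cfg, expected = expected)
}

#' Start an in-process archive server for testing
#'
#' Launches a background R process that serves the archived assets of
#' `config_path` (see [archive_assets()]) on an OS-assigned port of the
#' loopback interface, and waits until the API responds.
#'
#' @param config_path Path to a genome configuration whose manifest exists.
#' @param timeout Seconds to wait for the server to come up.
#' @return An object of class `ephemeral_server`: list with `url`, `port`
#'   and the background `process`. Stop it with [stop_ephemeral_server()].
#' @export
ephemeral_server <- function(config_path, timeout = 30) {
  if (!file.exists(manifest_path_for(config_path))) {
    abort_missing(sprintf(
      "no server manifest beside '%s'; run archive_assets() first", config_path
    ), "manifest")
  }
  port <- httpuv::randomPort(host = "127.0.0.1")
  px <- callr::r_bg(
    function(config_path, host, port) {
      refassets::run_asset_server(config_path, host, port)
    },
    args = list(config_path = config_path, host = "127.0.0.1", port = port),
    supervise = TRUE
  )
  url <- sprintf("http://127.0.0.1:%d", port)
  deadline <- Sys.time() + timeout
  repeat {
    if (!px$is_alive()) {
      err <- paste(px$read_all_error_lines(), collapse = "\n")
      refassets_abort(sprintf("ephemeral server failed to start:\n%s", err),
                      "refassets_error")
    }
    ok <- tryCatch({
      res <- http_get(paste0(url, "/v2/genomes"))
      identical(res$status_code, 200L)
    }, error = function(e) FALSE)
    if (ok) break
    if (Sys.time() > deadline) {
      px$kill()
      refassets_abort("ephemeral server did not come up in time", "refassets_error")
    }
    Sys.sleep(0.1)
  }
  structure(list(url = url, port = port, process = px),
            class = "ephemeral_server")
}

#' Stop an ephemeral test server
#'
#' @param server An `ephemeral_server` object.
#' @return Invisibly `TRUE`.
#' @export
stop_ephemeral_server <- function(server) {
  stopifnot(inherits(server, "ephemeral_server"))
  server$process$kill()
  invisible(TRUE)
}
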