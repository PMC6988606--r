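# Shared test helpers: temporary workspaces, tree snapshots for atomicity
# assertions, and random registry-path generation.

local_tmpdir <- function(env = parent.frame()) {
  td <- tempfile("refassets_test_")
  dir.create(td)
  withr::defer(unlink(td, recursive = TRUE), envir = env)
  td
}

# Full state of a directory tree: every file with its content hash, plus the
# directory set, so "byte-identical" claims are checkable.
snapshot_tree <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE))
  hashes <- vapply(files, function(f) {
    fp <- file.path(root, f)
    if (dir.exists(fp)) "<dir>" else digest::digest(fp, algo = "sha256", file = TRUE)
  }, "")
  dirs <- sort(setdiff(list.dirs(root, recursive = TRUE, full.names = FALSE), ""))
  list(files = hashes, dirs = dirs)
}

random_token <- function(min_len = 1L, max_len = 12L) {
  alphabet <- c(LETTERS, letters, 0:9, "_", "-")
  n <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_registry_string <- function() {
  s <- paste0(random_token(), "/", random_token())
  if (runif(1) < 0.4) s <- paste0(s, ".", random_token())
  if (runif(1) < 0.6) s <- paste0(s, ":", random_token())
  s
}

# A built single-genome workspace: config with one fasta asset.
make_built_workspace <- function(env = parent.frame(), seed = 11L,
                                 genome = "genome1") {
  td <- local_tmpdir(env)
  config_path <- file.path(td, "config.yaml")
  cfg <- init_config(config_path, file.path(td, "genomes"))
  fa_path <- file.path(td, "input.fa.gz")
  write_fasta(generate_fasta(3L, c(100L, 400L), line_width = 50L, seed = seed),
              fa_path)
  cfg <- build_asset(cfg, sprintf("%s/fasta", genome),
                     files = list(fasta = fa_path))$config
  write_config(cfg, config_path)
  list(root = td, config_path = config_path, config = cfg,
       genome = genome, fasta_input = fa_path)
}

run_cli_quietly <- function(argv, env = character()) {
  suppressMessages(run_cli(argv, env = env))
}
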