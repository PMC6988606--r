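# `samtools faidx` serves as the independent FAI oracle throughout.
faidx_oracle <- function(fasta_path) {
  status <- system2("samtools", c("faidx", fasta_path),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  readLines(paste0(fasta_path, ".fai"))
}

test_that("the recipe roster includes fasta and the declarative index recipes", {
  recipes <- list_recipes()
  expect_true(all(c("fasta", "bowtie2_index", "hisat2_index", "bwa_index")
                  %in% recipes$name))
  expect_true(all(nzchar(recipes$requirements)))
  expect_identical(recipes$kind[recipes$name == "fasta"], "internal")
})

test_that("requirements are described exactly as declared", {
  req <- describe_requirements("fasta")
  expect_identical(req$files, "fasta")
  expect_length(req$assets, 0L)

  req <- describe_requirements("bowtie2_index")
  expect_identical(req$assets, "fasta")
  expect_identical(req$params, c(threads = "1"))

  err <- expect_error(describe_requirements("no_such_recipe"),
                      class = "refassets_missing_error")
  expect_match(conditionMessage(err), "fasta")  # lists known names
})

test_that("build_fasta matches the FAI worked example", {
  td <- local_tmpdir()
  writeLines(">chr1\nACGT", file.path(td, "mini.fa"))
  out <- build_fasta(file.path(td, "mini.fa"), td, name = "mini")
  expect_identical(readLines(out[["fai"]]), "chr1\t4\t6\t4\t5")
  expect_identical(readLines(out[["chrom_sizes"]]), "chr1\t4")
  expect_identical(readLines(out[["fasta"]]), c(">chr1", "ACGT"))
})

test_that("gzipped and plain input with identical content build identically", {
  td <- local_tmpdir()
  text <- generate_fasta(4L, c(50L, 120L), line_width = 40L, seed = 5L)
  write_fasta(text, file.path(td, "p.fa"))
  write_fasta(text, file.path(td, "g.fa.gz"))
  d1 <- file.path(td, "out1"); dir.create(d1)
  d2 <- file.path(td, "out2"); dir.create(d2)
  o1 <- build_fasta(file.path(td, "p.fa"), d1, name = "x")
  o2 <- build_fasta(file.path(td, "g.fa.gz"), d2, name = "x")
  for (k in c("fasta", "fai", "chrom_sizes")) {
    expect_identical(readLines(o1[[k]]), readLines(o2[[k]]))
  }
})

test_that("FAI output is byte-identical to the samtools oracle on random input", {
  td <- local_tmpdir()
  widths <- c(1L, 7L, 80L)
  for (i in seq_along(widths)) {
    fa <- generate_fasta(10L, c(1L, 200L), line_width = widths[i],
                         seed = 100L + i)
    path <- file.path(td, sprintf("r%d.fa", i))
    write_fasta(fa, path)
    out_dir <- file.path(td, sprintf("out%d", i)); dir.create(out_dir)
    built <- build_fasta(path, out_dir, name = sprintf("r%d", i))
    expect_identical(readLines(built[["fai"]]), faidx_oracle(path))
  }
})

test_that("build_fasta rejects inputs FAI cannot represent", {
  td <- local_tmpdir()
  writeLines(">a\nACGTACGT\nACG\nACGTACGT", file.path(td, "ragged.fa"))
  expect_error(build_fasta(file.path(td, "ragged.fa"), td),
               class = "refassets_build_error")

  writeLines(">a\nACGT\n>a\nGGGG", file.path(td, "dup.fa"))
  err <- expect_error(build_fasta(file.path(td, "dup.fa"), td),
                      class = "refassets_build_error")
  expect_match(conditionMessage(err), "duplicate")

  file.create(file.path(td, "empty.fa"))
  expect_error(build_fasta(file.path(td, "empty.fa"), td),
               class = "refassets_build_error")

  writeLines("ACGT", file.path(td, "headerless.fa"))
  expect_error(build_fasta(file.path(td, "headerless.fa"), td),
               class = "refassets_build_error")

  writeLines(">only_header", file.path(td, "noseq.fa"))
  expect_error(build_fasta(file.path(td, "noseq.fa"), td),
               class = "refassets_build_error")
})

test_that("build_asset materializes, registers, and every seek key resolves", {
  td <- local_tmpdir()
  cfg <- init_config(file.path(td, "c.yaml"), file.path(td, "genomes"))
  write_fasta(generate_fasta(2L, c(60L, 90L), seed = 8L),
              file.path(td, "in.fa.gz"))
  res <- build_asset(cfg, "hg38/fasta", files = list(fasta = file.path(td, "in.fa.gz")))
  cfg <- res$config

  for (key in c("fasta", "fai", "chrom_sizes", "dir")) {
    p <- seek_asset(cfg, paste0("hg38/fasta.", key))
    expect_true(file.exists(p), info = key)
  }
  expect_identical(res$entry$asset_digest,
                   compute_asset_digest(seek_asset(cfg, "hg38/fasta.dir")))

  # the produced file set equals the declared outputs (plus the build log)
  produced <- list.files(seek_asset(cfg, "hg38/fasta.dir"), all.files = TRUE,
                         no.. = TRUE)
  expect_setequal(produced, c("hg38.fa", "hg38.fa.fai", "hg38.chrom.sizes",
                              "_build_log.yaml"))

  expect_error(build_asset(cfg, "hg38/fasta",
                           files = list(fasta = file.path(td, "in.fa.gz"))),
               class = "refassets_exists_error")
})

test_that("missing required inputs fail before any write", {
  td <- local_tmpdir()
  cfg <- init_config(file.path(td, "c.yaml"), file.path(td, "genomes"))
  before <- snapshot_tree(cfg$genome_folder)
  err <- expect_error(build_asset(cfg, "hg38/fasta"),
                      class = "refassets_build_error")
  expect_match(conditionMessage(err), "fasta")
  expect_identical(snapshot_tree(cfg$genome_folder), before)
})

test_that("building twice from the same input yields identical digests", {
  td <- local_tmpdir()
  write_fasta(generate_fasta(3L, c(40L, 80L), seed = 21L),
              file.path(td, "in.fa"))
  digests <- vapply(c("one", "two"), function(w) {
    root <- file.path(td, w)
    dir.create(root)
    cfg <- init_config(file.path(root, "c.yaml"), file.path(root, "genomes"))
    build_asset(cfg, "g1/fasta",
                files = list(fasta = file.path(td, "in.fa")))$entry$asset_digest
  }, "")
  expect_identical(digests[["one"]], digests[["two"]])
})

test_that("build followed by remove restores the genome folder exactly", {
  ws <- make_built_workspace()
  cfg <- ws$config
  before <- snapshot_tree(cfg$genome_folder)
  write_fasta(generate_fasta(2L, c(30L, 60L), seed = 31L),
              file.path(ws$root, "second.fa"))
  cfg <- build_asset(cfg, "other/fasta",
                     files = list(fasta = file.path(ws$root, "second.fa")))$config
  cfg <- remove_asset(cfg, "other/fasta")
  expect_identical(snapshot_tree(cfg$genome_folder), before)
})

test_that("recipes requiring prerequisite assets insist they exist first", {
  td <- local_tmpdir()
  cfg <- init_config(file.path(td, "c.yaml"), file.path(td, "genomes"))
  err <- expect_error(build_asset(cfg, "hg38/bowtie2_index"),
                      class = "refassets_build_error")
  expect_match(conditionMessage(err), "build or pull")
})

test_that("command templates render fully or are refused at execution", {
  r <- get_recipe("bowtie2_index")
  req <- build_request("hg38/bowtie2_index")
  cmd <- render_command(r, req, list(fasta = "/g/f.fa", output_dir = "/out"))
  expect_match(cmd, "/g/f.fa", fixed = TRUE)
  expect_match(cmd, "/out/hg38", fixed = TRUE)
  expect_match(cmd, "--threads 1", fixed = TRUE)  # default substituted

  req2 <- build_request("hg38/bowtie2_index", params = list(threads = "8"))
  expect_match(render_command(r, req2, list(fasta = "f", output_dir = "o")),
               "--threads 8", fixed = TRUE)

  # unresolved placeholder at render time is an error
  expect_error(render_command(r, req, list(output_dir = "/out")),
               class = "refassets_error")

  # executing a declarative recipe is refused without the explicit flag
  ws <- make_built_workspace()
  err <- expect_error(build_asset(ws$config,
                                  paste0(ws$genome, "/bowtie2_index")),
                      class = "refassets_build_error")
  expect_match(conditionMessage(err), "not supported")
})

test_that("undeclared placeholders fail at recipe registration, not render", {
  expect_error(
    recipe("bad", "0.1", "desc",
           outputs = list(out = "{genome}.bin"),
           default_seek_key = "out",
           procedure = list(kind = "command_template",
                            command = "tool {mystery_input} out")),
    class = "refassets_error"
  )
  expect_error(
    recipe("bad2", "0.1", "desc",
           outputs = list(out = "x"),
           default_seek_key = "nope",
           procedure = list(kind = "internal", entry = "f")),
    class = "refassets_error"
  )
})
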