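test_that("init creates an empty config and refuses to overwrite", {
  td <- local_tmpdir()
  path <- file.path(td, "config.yaml")
  cfg <- init_config(path, file.path(td, "genomes"),
                     servers = c("http://a.example", "http://b.example"))
  expect_true(file.exists(path))
  expect_length(list_local(cfg), 0L)

  reloaded <- load_config(path)
  expect_identical(reloaded$genome_servers,
                   c("http://a.example", "http://b.example"))
  expect_length(list_local(reloaded), 0L)

  expect_error(init_config(path, file.path(td, "genomes")),
               class = "refassets_exists_error")
})

test_that("config location resolution: explicit beats REFGENIE beats nothing", {
  expect_identical(
    resolve_config_location("/a/b.yaml", environment = c(REFGENIE = "/c.yaml")),
    "/a/b.yaml"
  )
  expect_identical(
    resolve_config_location(NULL, environment = c(REFGENIE = "/c.yaml")),
    "/c.yaml"
  )
  err <- expect_error(
    resolve_config_location(NULL, environment = character()),
    class = "refassets_usage_error"
  )
  expect_match(conditionMessage(err), "REFGENIE")
})

test_that("write(load(f)) is byte-identical for canonically formatted files", {
  ws <- make_built_workspace()
  before <- readBin(ws$config_path, "raw", file.size(ws$config_path))
  write_config(load_config(ws$config_path), ws$config_path)
  after <- readBin(ws$config_path, "raw", file.size(ws$config_path))
  expect_identical(after, before)
})

test_that("malformed or version-incompatible files give schema errors, file untouched", {
  td <- local_tmpdir()
  path <- file.path(td, "broken.yaml")
  writeLines("config_version: '1.0'\ngenome_folder: /x\ngenomes:\n  hg38:\n    assets:", path)
  before <- readBin(path, "raw", file.size(path))
  err <- expect_error(load_config(path), class = "refassets_schema_error")
  expect_match(conditionMessage(err), "hg38")
  expect_identical(readBin(path, "raw", file.size(path)), before)

  writeLines("genome_folder: /x", file.path(td, "missing.yaml"))
  err <- expect_error(load_config(file.path(td, "missing.yaml")),
                      class = "refassets_schema_error")
  expect_match(conditionMessage(err), "config_version")

  writeLines("config_version: '9.0'\ngenome_folder: /x\ngenomes: {}",
             file.path(td, "vers.yaml"))
  expect_error(load_config(file.path(td, "vers.yaml")),
               class = "refassets_schema_error")

  writeLines("seek: [unclosed", file.path(td, "junk.yaml"))
  expect_error(load_config(file.path(td, "junk.yaml")),
               class = "refassets_schema_error")
})

test_that("add registers in place, computes the digest, and seeks back", {
  td <- local_tmpdir()
  cfg <- init_config(file.path(td, "c.yaml"), file.path(td, "genomes"))
  ext <- file.path(td, "elsewhere")   # outside the genome folder
  dir.create(ext)
  writeLines("x\t1", file.path(ext, "ann.tsv"))

  cfg <- add_asset(cfg, "hg38/annotation", ext,
                   seek_keys = list(annotation = "ann.tsv"))
  expect_identical(seek_asset(cfg, "hg38/annotation"),
                   file.path(normalizePath(ext, winslash = "/"), "ann.tsv"))
  expect_identical(seek_asset(cfg, "hg38/annotation.dir"),
                   normalizePath(ext, winslash = "/"))

  entry <- cfg$genomes$hg38$assets$annotation$tags$default
  expect_identical(entry$asset_digest, compute_asset_digest(ext))

  expect_error(add_asset(cfg, "hg38/annotation", ext),
               class = "refassets_exists_error")
  expect_silent(cfg <- add_asset(cfg, "hg38/annotation", ext, force = TRUE))
})

test_that("remove deregisters, deletes only inside the genome folder, prunes levels", {
  ws <- make_built_workspace()
  cfg <- ws$config
  asset_dir <- seek_asset(cfg, paste0(ws$genome, "/fasta.dir"))
  expect_true(dir.exists(asset_dir))

  cfg <- remove_asset(cfg, paste0(ws$genome, "/fasta"))
  expect_false(dir.exists(asset_dir))
  expect_length(list_local(cfg), 0L)  # last tag removes asset and genome level
  expect_error(seek_asset(cfg, paste0(ws$genome, "/fasta")),
               class = "refassets_missing_error")

  # externally registered assets are deregistered only
  ext <- file.path(ws$root, "ext")
  dir.create(ext)
  writeLines("a", file.path(ext, "f.txt"))
  cfg <- add_asset(cfg, "hg19/ann", ext, seek_keys = list(ann = "f.txt"))
  cfg <- remove_asset(cfg, "hg19/ann")
  expect_true(file.exists(file.path(ext, "f.txt")))

  err <- expect_error(remove_asset(cfg, "nowhere/fasta"),
                      class = "refassets_missing_error")
  expect_identical(err$level, "genome")
})

test_that("tagging creates an alias: same path, same digest, both seekable", {
  ws <- make_built_workspace()
  cfg <- tag_asset(ws$config, paste0(ws$genome, "/fasta"), "v1")
  expect_identical(seek_asset(cfg, paste0(ws$genome, "/fasta:v1")),
                   seek_asset(cfg, paste0(ws$genome, "/fasta:default")))
  tags <- cfg$genomes[[ws$genome]]$assets$fasta$tags
  expect_identical(tags$v1$asset_digest, tags$default$asset_digest)
  # default tag is not re-pointed
  expect_identical(cfg$genomes[[ws$genome]]$assets$fasta$default_tag, "default")

  expect_error(tag_asset(cfg, paste0(ws$genome, "/fasta"), "v1"),
               class = "refassets_exists_error")
  expect_error(tag_asset(cfg, paste0(ws$genome, "/nope"), "v2"),
               class = "refassets_missing_error")
  expect_error(tag_asset(cfg, paste0(ws$genome, "/fasta"), "default"),
               class = "refassets_usage_error")
})

test_that("seek distinguishes the failing level and returns bare paths", {
  ws <- make_built_workspace()
  cfg <- ws$config
  path <- seek_asset(cfg, paste0(ws$genome, "/fasta"))
  expect_false(grepl("\n", path))
  expect_true(startsWith(path, "/"))
  expect_true(file.exists(path))  # default seek key is the sequence file
  expect_match(path, "\\.fa$")

  levels <- list(
    list(rp = "nope/fasta", level = "genome"),
    list(rp = paste0(ws$genome, "/nope"), level = "asset"),
    list(rp = paste0(ws$genome, "/fasta:nope"), level = "tag"),
    list(rp = paste0(ws$genome, "/fasta.nope"), level = "seek_key")
  )
  for (case in levels) {
    err <- expect_error(seek_asset(cfg, case$rp),
                        class = "refassets_missing_error")
    expect_identical(err$level, case$level)
  }
})

test_that("random add/tag/remove sequences persist with full fidelity", {
  td <- local_tmpdir()
  path <- file.path(td, "c.yaml")
  cfg <- init_config(path, file.path(td, "genomes"))
  pool <- file.path(td, "pool")
  dir.create(pool)

  withr::with_seed(99, {
    for (i in 1:60) {
      op <- sample(c("add", "tag", "remove"), 1L, prob = c(0.5, 0.25, 0.25))
      listing <- list_local(cfg)
      if (op == "add" || !length(listing)) {
        g <- paste0("g", sample.int(4, 1))
        a <- paste0("a", sample.int(4, 1))
        t <- paste0("t", sample.int(3, 1))
        d <- file.path(pool, paste0("d", i))
        dir.create(d)
        writeLines(as.character(i), file.path(d, "data.txt"))
        cfg <- add_asset(cfg, sprintf("%s/%s:%s", g, a, t), d, force = TRUE)
      } else {
        g <- sample(names(listing), 1L)
        at <- sample(listing[[g]], 1L)
        rp <- sprintf("%s/%s", g, at)
        if (op == "tag") {
          cfg <- tag_asset(cfg, rp, paste0("alias", i), force = TRUE)
        } else {
          cfg <- remove_asset(cfg, rp)
        }
      }
      write_config(cfg, path)
      expect_identical(list_local(load_config(path)), list_local(cfg))
    }
  })
})

test_that("interleaved locked mutations from two processes all land", {
  td <- local_tmpdir()
  path <- file.path(td, "c.yaml")
  init_config(path, file.path(td, "genomes"))
  # each worker registers 4 external asset dirs under its own genome
  worker <- function(config_path, genome, pool) {
    for (i in 1:4) {
      d <- file.path(pool, paste0(genome, "_", i))
      dir.create(d, recursive = TRUE)
      writeLines(paste(genome, i), file.path(d, "f.txt"))
      refassets::with_config_lock(config_path, function(cfg) {
        refassets::add_asset(cfg, sprintf("%s/asset%d", genome, i), d)
      })
    }
    TRUE
  }
  pool <- file.path(td, "pool")
  dir.create(pool)
  p1 <- callr::r_bg(worker, args = list(path, "left", pool))
  p2 <- callr::r_bg(worker, args = list(path, "right", pool))
  p1$wait(30000); p2$wait(30000)
  expect_true(p1$get_result())
  expect_true(p2$get_result())
  listing <- list_local(load_config(path))
  expect_setequal(names(listing), c("left", "right"))
  expect_length(listing$left, 4L)
  expect_length(listing$right, 4L)
})
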