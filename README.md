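# refassets

Reference genome asset management, archiving and retrieval for R.

High-throughput sequencing pipelines depend on resources derived from a
reference genome assembly — the sequences themselves, aligner indexes
(bowtie2, hisat2, bwa), annotation bundles. Every group stores these
somewhere different, so tools hard-code paths and sharing breaks. refassets
organizes such resources ("assets") under one standard on-disk layout,
names each one with a human-readable **registry path**

```
{genome}/{asset}[.{seek_key}][:{tag}]        e.g.  hg38/fasta.chrom_sizes:default
```

and tracks them in a YAML **genome configuration file**, so that any
pipeline can locate any asset with a single portable lookup
(`seek_asset()`, or `refassets seek` from the shell). Assets are obtained
two ways:

* **build** — recipes materialize an asset from arbitrary local inputs
  under `{genome_folder}/{genome}/{asset}/{tag}/`. The `fasta` recipe is
  fully internal: it uncompresses the input, computes the 5-column FAI
  index (name, length in bases, byte offset of the first base, bases per
  line, bytes per line) and a `chrom.sizes` table. Aligner-index recipes
  are shipped as declarative command templates.
* **pull** — a companion archive server compresses each asset into an
  individual gzip tarball and serves it, with metadata, over a small
  REST-style API (`/v2/genomes`, `/v2/assets`,
  `/v2/asset/{genome}/{asset}/archive|digest|recipe|log|attributes`,
  OpenAPI 3.0 description at `/openapi.json`). The client downloads,
  verifies the tarball bytes and the unpacked tree against the advertised
  digests, unpacks into the standard layout, and registers the asset.

Identity and provenance: every asset carries an order- and
location-independent content digest (SHA-256 over the sorted sequence of
(relative path, per-file SHA-256) pairs) plus a `_build_log.yaml` recording
inputs, input digests, software versions, timestamps, and the final digest
— so two assets with the same name can always be distinguished, and a built
asset can be traced back to its inputs.

## Worked example

```r
library(refassets)

td <- "/tmp/readme_demo"; dir.create(td)
cfg_path <- file.path(td, "genome_config.yaml")
cfg <- init_config(cfg_path, file.path(td, "genomes"))

# a small synthetic genome (2 sequences), gzip-compressed
write_fasta(generate_fasta(2, c(800, 1200), line_width = 60, seed = 42),
            file.path(td, "toy.fa.gz"))

res <- build_asset(cfg, "toy/fasta", files = list(fasta = file.path(td, "toy.fa.gz")))
cfg <- res$config; write_config(cfg, cfg_path)

seek_asset(cfg, "toy/fasta.chrom_sizes")
#> [1] "/tmp/readme_demo/genomes/toy/fasta/default/toy.chrom.sizes"
writeLines(readLines(seek_asset(cfg, "toy/fasta.chrom_sizes")))
#> chr1	848
#> chr2	1162
writeLines(readLines(seek_asset(cfg, "toy/fasta.fai")))
#> chr1	848	6	60	61
#> chr2	1162	875	60	61
format_digest(res$entry$asset_digest)
#> [1] "4ee6f164631731b326783f84d1846fc6"
```

The chrom.sizes rows are sequence name and length in bases, in input order;
the FAI row `chr1 848 6 60 61` says chr1 has 848 bases, its first base is
at byte offset 6 (after `>chr1\n`), with 60 bases per line and 61 bytes per
line including the newline. The digest (shown truncated to 32 hex
characters) identifies the exact file contents of the asset directory.

Serving and pulling:

```r
archive_assets(cfg_path)               # tarball per asset + server manifest
srv <- ephemeral_server(cfg_path)      # background server on a random port

client <- init_config("/tmp/client.yaml", "/tmp/client_genomes", servers = srv$url)
pulled <- pull_asset(client, "toy/fasta")
identical(pulled$entry$asset_digest, res$entry$asset_digest)
#> [1] TRUE
stop_ephemeral_server(srv)
```

From the shell (launcher at `system.file("cli", "refassets", package = "refassets")`):

```sh
export REFGENIE=/tmp/readme_demo/genome_config.yaml
refassets list
#> genome  assets
#> toy     fasta:default
fasta_path=$(refassets seek toy/fasta)   # bare path, command-substitution safe
```

Available recipes (`list_recipes()`):

```
           name             kind                     requirements
1 bowtie2_index command_template assets: fasta; params: threads=1
2     bwa_index command_template                    assets: fasta
3         fasta         internal                     files: fasta
4  hisat2_index command_template assets: fasta; params: threads=1
```

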