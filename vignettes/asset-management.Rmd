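---
title: "Managing reference genome assets: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing reference genome assets: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refassets)
```

## The problem

Sequence-analysis pipelines need genome-derived resources — the assembly
sequences, aligner indexes, annotation bundles — and need to find them by
name rather than by hard-coded path. refassets treats each such resource as
an *asset*: a directory of related files tied to one genome assembly,
identified by a registry path and tracked in a YAML genome configuration
file. This vignette records the contracts and the design choices that were
genuinely open, so that an independent implementation could reproduce the
behavior bit-for-bit where that matters.

## Registry paths

The grammar is `genome/asset[.seek_key][:tag]`. The genome acts as a
namespace; the tag names a version of the asset; the optional seek key
addresses one file inside the asset directory. A missing tag always means
the literal tag `default`, which is what build and pull assign when no tag
is given, so `format(parse(s))` yields a canonical form in which the tag is
always explicit.

Two choices here were ours, not forced:

* **Token alphabet** `[A-Za-z0-9_-]`. Nothing in the problem statement pins
  the legal character set, but tokens become filesystem path components
  verbatim, so `/`, `:`, `.` and whitespace must be excluded and a
  conservative portable alphabet is the safe closure of that constraint.
* **Seek-key syntax** as a dot suffix on the asset (`hg38/fasta.fai:tag`).
  `seek` must return a directly usable file path, yet an asset is a
  directory and, e.g., a bowtie2 index is addressed by a file *prefix*
  inside it — per-file addressing needs syntax, and the dot suffix keeps
  the genome/asset/tag structure intact. The reserved seek key `dir`
  (always present, mapping to `.`) addresses the directory itself.

## The genome configuration file

A YAML document with fixed key order:
`config_version`, `genome_folder`, `genome_servers` (ordered list),
`genomes → {genome} → assets → {asset} → {default_tag, tags → {tag} →
{asset_path, seek_keys, asset_digest, build_log}}`. Canonical rendering is
two-space-indent YAML emitted in that order, so `write(load(f))` is
byte-identical for canonical files and hand-edits that keep the schema
valid still load. An unsupported major `config_version` is a hard error;
malformed entries produce a schema error listing the offending keys.

Concurrency: the CLI and the archive server may operate on the same file,
so every mutation runs under an exclusive advisory lock on a sidecar
`<config>.lock` (`with_config_lock()`), and every write is atomic
(temp-file-then-rename in the same directory). Readers take no lock: they
either see the old file or the new one, never a torn one.

Semantics chosen where the behavior was open:

* `tag` creates an **alias** — a second tag entry referencing the same
  directory and digest. Copying multi-gigabyte indexes to version them
  would defeat the purpose of centralized storage. Tagging does **not**
  re-point `default_tag`.
* `remove` deletes files only when the asset directory lies inside the
  genome folder; assets registered in place elsewhere (`add_asset` on an
  external directory) are deregistered only. Removing the last tag removes
  the asset entry (and an emptied genome entry); removing the default tag
  while others remain re-points `default_tag` to the lexicographically
  first survivor.
* Plain `seek genome/asset` resolves the asset's *default seek key* (for a
  `fasta` asset, the sequence file), not the directory — the shell idiom
  `path=$(... seek hg38/fasta)` expects a usable path. The default key is
  defined by the recipe of the same name; for recipe-less assets, a key
  named like the asset wins, then a sole non-`dir` key, then `dir`.

## Recipes and building

A recipe declares required input files, prerequisite assets, parameters
with defaults, outputs (seek key → path template relative to the asset
directory), a default seek key, and a procedure. Templates may reference
`{genome}`, `{asset}`, `{tag}`, `{output_dir}` and any declared name;
referencing an undeclared placeholder fails at recipe *registration*, not
at render time. Recipes live in a packaged YAML manifest
(`inst/extdata/recipes.yaml`), so declarative recipes can be added without
code changes; each carries a version string recorded in the build log
(bumping it never invalidates existing assets).

One recipe is fully internal — `fasta` — because it is the root of the
dependency graph and must run with no third-party binaries. The three
aligner-index recipes (bowtie2, hisat2, bwa) are command templates that
render to real build commands but are refused at execution unless
`allow_execution = TRUE`; the test suite never executes them.

The `fasta` procedure reads plain or gzip-compressed FASTA (detected by
the 1f 8b magic bytes) and writes:

* `{genome}.fa` — the uncompressed input, line structure preserved, LF
  endings;
* `{genome}.fa.fai` — the 5-column FAI dialect: name (first
  whitespace-delimited token of the header), length in bases, byte offset
  of the first base, bases per line, bytes per line (= bases + 1, since
  outputs are LF-terminated and uncompressed — the compressed-offset
  columns of the 6/7-column dialect do not apply);
* `{genome}.chrom.sizes` — `name<TAB>length` rows in input order (stable
  and matching the sequence file layout, rather than lexicographic).

Inputs FAI cannot represent are rejected: duplicate sequence names, ragged
line lengths within a record (any non-final line differing from the
first, or a final line longer than it), headers without a name, records
with no sequence, empty files. The test oracle is `samtools faidx` run on
the same bytes; equivalence is byte-for-byte.

**Failure atomicity.** Builds write into a hidden temporary sibling of the
tag directory and rename into place only after the digest and build log
are written; on failure the temporary directory and any genome/asset
directory levels the build created are removed, leaving the genome folder
and the configuration exactly as before. The same pattern applies to pull.

## Digests and provenance

The asset digest must identify content regardless of where the directory
sits or how the filesystem enumerates it. The construction (pinned
bit-exactly, since cross-implementation reproducibility is the point):

1. enumerate all regular files recursively (hidden files included),
   as `/`-separated relative paths, excluding basenames starting with
   `_build_log`;
2. sort the paths bytewise (C collation, locale-independent);
3. per file, SHA-256 of the raw bytes — no newline or encoding
   normalization, assets are binary-opaque;
4. SHA-256 of the concatenation of `"<relpath>\t<hex>\n"` lines.

An empty directory digests to SHA-256 of the empty string
(`e3b0c4…b855`; the test suite pins the constant from an independent
computation). The build log is excluded so that the digest can be recorded
*inside* the log — including it would be circular. Full 64-hex digests are
stored; displays truncate to 32. One consequence worth noting: output
filenames embed the genome name, so building the same input under a
different genome name yields a different digest — by design, since the
digest covers relative paths.

The build log (`_build_log.yaml`, fixed name, inside the asset directory)
records the registry path, recipe name and version, each input with its
own content digest, software versions, start/finish timestamps (ISO-8601
UTC), and the final asset digest; read/write round-trips exactly.

## Archiving and serving

`archive_assets()` compresses each (asset, tag) into an individual gzip
tarball under `{genome_folder}/_archive/{genome}/{asset}__{tag}.tgz` and
writes a manifest beside the config recording, per entry: registry path,
archive path, the SHA-256 of the tarball bytes, the archive size, the
content listing, the asset digest, the seek keys, and the recipe name when
a build log is present. The tarball root is the tag directory's contents —
no leading path components — so the client alone chooses the destination
from the registry path. Re-archiving skips entries whose asset digest is
unchanged (idempotence).

The server is read-only and speaks JSON plus `application/octet-stream`
for archives, with endpoints under a uniform `/v2` prefix (unprefixed
forms redirect with 307) and an OpenAPI 3.0 document at `/openapi.json`.
The archive endpoint takes the tag as a query parameter defaulting to the
asset's default tag — the endpoint path itself carries no tag segment, and
the query-parameter form keeps the path stable. Not-found responses carry
a machine-readable `level` (genome vs asset vs tag) so clients can report
precisely.

Because R is single-threaded, the test harness's "in-process" server is a
supervised child R process (`callr`) bound to a random loopback port; the
serving code itself (`build_app()`) is a plain httpuv application and can
equally run blocking in a dedicated process (`run_asset_server()`).

## Pulling

`pull_asset()` tries the configured servers in order (first success wins),
streams the tarball to a temporary file, verifies the bytes against the
advertised archive digest, unpacks to a hidden sibling of the target
directory, verifies the unpacked tree against the advertised asset digest,
renames into place, and registers seek keys and digest from the server's
attributes. Either verification failure aborts with an integrity error and
rolls back every file and directory level the pull created. A local tag
that already exists is refused without `force` — when server and local
copies share a name but differ in digest, silently replacing either would
defeat the provenance model. Download resume is deliberately not
supported: archives at the scale this serves are small, and resume logic
would complicate the integrity story.

## Synthetic data: what it does and does not establish

`generate_fasta()` emulates the one property of real genome files the
machinery depends on: FASTA structure — named records, fixed line width
with a shorter final line, ACGTN alphabet (N at 2%, mimicking occasional
ambiguous calls). Record lengths are uniform in the requested range;
defaults in the test fixtures (a few records of 10²–10³ bases) keep the
full build→archive→serve→pull cycle under seconds. The randomness source
is R's default Mersenne-Twister, seeded locally with the caller's RNG
state saved and restored, so every fixture derives solely from seed and
parameters.

What it does **not** emulate: repeats, GC skew, chromosome-scale sizes,
soft-masking, multi-gigabyte I/O behavior, real aligner index contents.
A green suite therefore establishes the management layer's contracts —
naming, layout, indexing arithmetic, digests, locking, archive/pull
integrity — not performance at genome scale, and not the correctness of
the external index builders, whose recipes are declarative only.

## Numerical / procedural choices

* Lock wait: 30 s default timeout on the sidecar lock; mutations are
  short (YAML write), so contention beyond that indicates a stuck process.
* Digest truncation: display-only, 32 hex chars; comparisons always use
  the full value.
* CLI exit codes: 0 success, 1 domain error, 2 usage error, 3
  network/integrity error; `seek` prints the bare path with no trailing
  newline; all diagnostics go to standard error.
* Tie-break when a removed default tag leaves several survivors:
  lexicographic (bytewise) minimum, for determinism.
* Server precedence on conflicting listings: the first configured server
  wins per genome.

## Known limitations

* No genome-identity aliasing (hg38 vs GRCh38 are distinct namespaces).
* No sequence-level (per-chromosome) checksums; identity is per-asset.
* No authentication, rate limiting, or resume on the server/client pair.
* Multi-filesystem asset storage works only via hand-edited absolute
  `asset_path` entries (which load fine, but no tooling manages them).
* Command-template recipes are executed only on explicit opt-in and are
  untested against the real external tools here.
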