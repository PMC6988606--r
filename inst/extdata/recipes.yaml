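# Packaged recipe manifest. Each recipe declares what an asset build needs
# (files, prerequisite assets, parameters with defaults), what it produces
# (seek keys -> output path templates, relative to the asset directory), and
# how (an internal procedure implemented by the package, or a declarative
# shell command template that is never executed unless execution is
# explicitly allowed).
#
# Template placeholders: {genome}, {asset}, {tag}, {output_dir}, plus every
# declared file, asset, and parameter name. Undeclared placeholders are an
# error at recipe registration time.
recipes:
  fasta:
    version: "0.1.0"
    description: >-
      Uncompressed genome sequences plus a FAI index and a chromosome-sizes
      table, built from a FASTA file (optionally gzip-compressed).
    required_files:
      - name: fasta
        description: FASTA file, plain or gzip-compressed
    required_assets: []
    required_params: []
    outputs:
      fasta: "{genome}.fa"
      fai: "{genome}.fa.fai"
      chrom_sizes: "{genome}.chrom.sizes"
    default_seek_key: fasta
    procedure:
      kind: internal
      entry: build_fasta
  bowtie2_index:
    version: "0.1.0"
    description: Genome index for the bowtie2 aligner, built with bowtie2-build.
    required_files: []
    required_assets:
      - fasta
    required_params:
      - name: threads
        default: "1"
    outputs:
      bowtie2_index: "{genome}"
    default_seek_key: bowtie2_index
    procedure:
      kind: command_template
      command: "bowtie2-build --threads {threads} {fasta} {output_dir}/{genome}"
  hisat2_index:
    version: "0.1.0"
    description: Genome index for the hisat2 aligner, built with hisat2-build.
    required_files: []
    required_assets:
      - fasta
    required_params:
      - name: threads
        default: "1"
    outputs:
      hisat2_index: "{genome}"
    default_seek_key: hisat2_index
    procedure:
      kind: command_template
      command: "hisat2-build -p {threads} {fasta} {output_dir}/{genome}"
  bwa_index:
    version: "0.1.0"
    description: Genome index for the bwa aligner, built with bwa index.
    required_files: []
    required_assets:
      - fasta
    required_params: []
    outputs:
      bwa_index: "{genome}.fa"
    default_seek_key: bwa_index
    procedure:
      kind: command_template
      command: "bwa index -p {output_dir}/{genome}.fa {fasta}"
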