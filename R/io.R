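# Readers and writers for the standard interchange formats used by the
# pipeline: FASTA (plain and aligned), GFF3 gene models, newick trees,
# outfmt-6-style homology hit tables (with taxonomy columns), SNP tables
# (TSV or VCF), and repeat-hit tables.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (plain or aligned; gaps preserved).
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header), `description` (remainder, possibly `""`) and `seq`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  tibble(
    id = sub("\\s.*$", "", headers),
    description = ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), ""),
    seq = unname(toupper(as.character(ss)))
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs Data frame with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  seqs <- as_tibble(seqs)
  headers <- seqs$id
  if ("description" %in% names(seqs)) {
    has_desc <- !is.na(seqs$description) & seqs$description != ""
    headers[has_desc] <- paste(seqs$id[has_desc], seqs$description[has_desc])
  }
  ss <- Biostrings::BStringSet(seqs$seq)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` and `exon` features and returns one row per exon with the
#' gene-level fields repeated. Coordinates are kept 1-based inclusive, the
#' GFF3 convention.
#'
#' @param path GFF3 file.
#' @return Tibble with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `source`, and `completeness` (NA when not annotated).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  genes <- df %>% filter(.data$type == "gene")
  exons <- df %>% filter(.data$type == "exon")
  meta <- tibble(
    gene_id = as.character(genes$ID),
    source = as.character(genes$source),
    completeness = if ("completeness" %in% names(genes))
      suppressWarnings(as.numeric(genes$completeness)) else NA_real_
  )
  exons %>%
    transmute(gene_id = as.character(unlist(.data$Parent)),
              contig = as.character(.data$seqnames),
              strand = as.character(.data$strand),
              start = as.integer(.data$start),
              end = as.integer(.data$end)) %>%
    left_join(meta, by = "gene_id") %>%
    arrange(.data$contig, .data$gene_id, .data$start)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature per gene (spanning its exons) and one `exon`
#' feature per exon, with `completeness` and any `merge_rule` provenance as
#' GFF3 attributes.
#'
#' @param models Exon-level gene model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @param provenance Optional tibble (`gene_id`, `rule`) from
#'   [reconcile_gene_models()], written as a `merge_rule` attribute.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, provenance = NULL) {
  models <- as_tibble(models)
  genes <- models %>%
    group_by(.data$gene_id) %>%
    summarise(contig = first(.data$contig), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              source = first(.data$source),
              completeness = first(.data$completeness), .groups = "drop")
  if (!is.null(provenance)) {
    genes <- left_join(genes, provenance[, c("gene_id", "rule")],
                       by = "gene_id")
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id,
    source = genes$source %||% "genomescape")
  if (!all(is.na(genes$completeness))) {
    gene_gr$completeness <- genes$completeness
  }
  if (!is.null(provenance)) gene_gr$merge_rule <- genes$rule
  exon_gr <- GenomicRanges::GRanges(
    seqnames = models$contig,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = models$strand,
    type = "exon",
    ID = paste0(models$gene_id, ".exon",
                stats::ave(seq_len(nrow(models)), models$gene_id,
                           FUN = seq_along)),
    Parent = models$gene_id)
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Read a homology hit table
#'
#' Tab-separated BLAST outfmt-6 dialect extended with taxonomy columns:
#' `query_id subject_id identity align_len mismatches gap_open qstart qend
#' sstart send evalue bitscore phylum is_metazoan is_coral`.
#'
#' @param path TSV file (a header line is detected and skipped).
#' @param min_identity Optional identity floor (percent); when supplied,
#'   hits below it are dropped, mirroring the upstream search filter.
#' @return Tibble of hits with logical taxonomy flags.
#' @export
read_hits <- function(path, min_identity = NULL) {
  cols <- c("query_id", "subject_id", "identity", "align_len", "mismatches",
            "gap_open", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore", "phylum", "is_metazoan", "is_coral")
  first <- readLines(path, n = 1)
  skip <- if (grepl("query_id", first, fixed = TRUE)) 1 else 0
  hits <- readr::read_tsv(path, col_names = cols, skip = skip,
                          show_col_types = FALSE)
  hits <- hits %>%
    mutate(is_metazoan = as.logical(.data$is_metazoan),
           is_coral = as.logical(.data$is_coral))
  if (any(hits$is_coral & !hits$is_metazoan)) {
    gs_abort("Taxonomy flags inconsistent: is_coral implies is_metazoan.",
             "bad_input")
  }
  if (!is.null(min_identity)) {
    hits <- filter(hits, .data$identity >= min_identity)
  }
  hits
}

#' Write a homology hit table
#' @param hits Hit tibble (see [read_hits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path, col_names = FALSE)
  invisible(path)
}

#' Read a biallelic SNP table
#'
#' Accepts either a 4-column TSV (`contig`, `pos`, `ref_count`,
#' `alt_count`) or a VCF with AD-style allele depths (biallelic rows only;
#' multi-allelic rows must be split upstream).
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"` (inferred from the extension by
#'   default).
#' @return Tibble with columns `contig`, `pos`, `ref_count`, `alt_count`.
#' @export
read_snps <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    snps <- readr::read_tsv(path,
                            col_names = c("contig", "pos", "ref_count",
                                          "alt_count"),
                            col_types = "ciii", comment = "#")
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      gs_abort("Reading VCF requires the vcfR package.", "bad_input")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    parts <- strsplit(ad, ",")
    snps <- tibble(
      contig = as.character(v@fix[, "CHROM"]),
      pos = as.integer(v@fix[, "POS"]),
      ref_count = as.integer(map_chr(parts, 1)),
      alt_count = as.integer(map_chr(parts, 2))
    )
  }
  if (any(snps$ref_count + snps$alt_count <= 0)) {
    gs_abort("Every SNP must have positive total depth.", "bad_input")
  }
  snps
}

#' Read repeat hits
#'
#' Tab-separated table with columns `family_id`, `contig`, `start`, `end`
#' (1-based inclusive), as produced by converting RepeatMasker `.out` or
#' BED output.
#'
#' @param path TSV file.
#' @return Tibble of repeat placements.
#' @export
read_repeat_hits <- function(path) {
  readr::read_tsv(path, col_names = c("family_id", "contig", "start", "end"),
                  col_types = "ccii", comment = "#")
}

#' Read a self-alignment hit table
#'
#' 12-column outfmt-6 dialect; columns 1-4 are used (`contig_a`,
#' `contig_b`, `identity` percent, `length` bp).
#'
#' @param path TSV file.
#' @return Tibble with columns `contig_a`, `contig_b`, `identity`, `length`.
#' @export
read_self_hits <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble(contig_a = as.character(x[[1]]), contig_b = as.character(x[[2]]),
         identity = as.numeric(x[[3]]), length = as.integer(x[[4]]))
}

#' Read an orthogroup count matrix
#'
#' OrthoFinder `Orthogroups.GeneCount.tsv` dialect: first column the
#' orthogroup id, one column per species, an optional `Total` column
#' (dropped).
#'
#' @param path TSV file with a header row.
#' @return Tibble with `family_id` plus one integer column per species.
#' @export
read_orthogroup_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "family_id"
  x[setdiff(names(x), "Total")]
}
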