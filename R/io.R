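## Readers/writers for the formats the pipeline touches.
##
## Coordinate convention: positions are 0-based forward-strand C coordinates
## internally, everywhere; a CpG dyad is the half-open interval [pos, pos+2).
## Conversion to/from 1-based or interval formats happens only here, at file
## boundaries. Reverse-strand records are re-keyed to their dyad's forward-C
## position at ingest so every module addresses a CpG by one coordinate.

check_path_writable <- function(path, overwrite) {
  if (file.exists(path) && !overwrite) {
    abort(paste0("refusing to overwrite existing file: ", path,
                 " (set overwrite = TRUE)"))
  }
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' Expects the tab-separated CpG-context report dialect: chromosome, 1-based
#' position of the measured cytosine, strand (`+`/`-`), methylated count,
#' unmethylated count, context, trinucleotide. Forward-strand records map to
#' `pos = position - 1`; reverse-strand records sit on the G of the dyad, so
#' they are re-keyed to the forward C at `pos = position - 2`.
#'
#' @param path File path.
#' @param sample_id Optional sample label added as a column.
#' @return Tibble of stranded CpG calls: `chrom`, `pos` (0-based forward C),
#'   `strand` (`"forward"`/`"reverse"`), `meth_count`, `unmeth_count`, and
#'   `sample_id` if given. An empty file yields an empty tibble.
#' @export
read_cytosine_report <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  empty <- tibble(
    chrom = character(), pos = integer(), strand = character(),
    meth_count = integer(), unmeth_count = integer()
  )
  if (file.size(path) == 0) {
    if (!is.null(sample_id)) empty$sample_id <- character()
    return(empty)
  }
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "position", "strand_sym", "meth_count",
                  "unmeth_count", "context", "trinucleotide"),
    col_types = "ciciicc", progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed cytosine report lines in ", path, ": ",
      paste(unique(probs$row), collapse = ", ")
    ))
  }
  bad_strand <- which(!raw$strand_sym %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("unknown strand symbol at line(s): ",
                 paste(head(bad_strand, 5), collapse = ", ")))
  }
  bad_counts <- which(raw$meth_count < 0 | raw$unmeth_count < 0 |
                        is.na(raw$meth_count) | is.na(raw$unmeth_count))
  if (length(bad_counts) > 0) {
    abort(paste0("negative or missing counts at line(s): ",
                 paste(head(bad_counts, 5), collapse = ", ")))
  }
  out <- tibble(
    chrom = raw$chrom,
    pos = as.integer(ifelse(raw$strand_sym == "+",
                            raw$position - 1L, raw$position - 2L)),
    strand = ifelse(raw$strand_sym == "+", "forward", "reverse"),
    meth_count = as.integer(raw$meth_count),
    unmeth_count = as.integer(raw$unmeth_count)
  )
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

#' Write a Bismark-style cytosine report
#'
#' Inverse of [read_cytosine_report()]: forward records are written at the
#' 1-based C position (`pos + 1`), reverse records at the 1-based G position
#' (`pos + 2`) with strand `-`.
#'
#' @param calls Stranded call tibble (`chrom`, `pos`, `strand`, `meth_count`,
#'   `unmeth_count`), one sample.
#' @param path Output path.
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path, overwrite = FALSE) {
  check_path_writable(path, overwrite)
  out <- calls |>
    arrange(.data$chrom, .data$pos, .data$strand) |>
    transmute(
      .data$chrom,
      position = ifelse(.data$strand == "forward", .data$pos + 1L, .data$pos + 2L),
      strand_sym = ifelse(.data$strand == "forward", "+", "-"),
      .data$meth_count, .data$unmeth_count,
      context = "CpG", trinucleotide = "CGN"
    )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read diploid genotypes from a VCF
#'
#' Parses a VCF (v4.2, GT fields) with `vcfR` and returns alternate-allele
#' dosages for biallelic SNVs. Multi-allelic and indel records are skipped and
#' counted; missing GT fields yield `NA` dosage and are counted.
#'
#' @param path VCF path.
#' @return Long tibble `snp_id`, `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `individual_id`, `dosage`, with attributes `n_skipped_records`
#'   (multi-allelic/indel) and `n_missing_gt`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% BASES & fix$ALT %in% BASES
  n_skipped <- sum(!keep)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  dosage_of <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."),
           NA_integer_,
           stringr::str_count(g, "1"))
  }
  dos <- apply(gt, 2, dosage_of)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(fix))
  out <- tibble(
    snp_id = rep(ids, ncol(gt)),
    chrom = rep(fix$CHROM, ncol(gt)),
    pos = rep(as.integer(fix$POS) - 1L, ncol(gt)),
    ref = rep(fix$REF, ncol(gt)),
    alt = rep(fix$ALT, ncol(gt)),
    individual_id = rep(colnames(gt), each = nrow(fix)),
    dosage = as.integer(dos)
  )
  attr(out, "n_skipped_records") <- n_skipped
  attr(out, "n_missing_gt") <- sum(is.na(out$dosage))
  out
}

#' Write diploid genotypes as VCF v4.2
#'
#' @param snps SNP table (`snp_id`, `chrom`, `pos` 0-based, `ref`, `alt`).
#' @param genotypes Long dosage tibble (`snp_id`, `individual_id`, `dosage`).
#' @param path Output path.
#' @param overwrite See [write_cytosine_report()].
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(snps, genotypes, path, overwrite = FALSE) {
  check_path_writable(path, overwrite)
  individuals <- unique(genotypes$individual_id)
  wide <- genotypes |>
    mutate(gt = dplyr::case_match(.data$dosage,
      0L ~ "0/0", 1L ~ "0/1", 2L ~ "1/1", .default = "./."
    )) |>
    select("snp_id", "individual_id", "gt") |>
    tidyr::pivot_wider(names_from = "individual_id", values_from = "gt")
  rows <- snps |>
    arrange(.data$chrom, .data$pos) |>
    left_join(wide, by = "snp_id")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=methleakr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individuals), collapse = "\t")
  )
  body <- paste(
    rows$chrom, rows$pos + 1L, rows$snp_id, rows$ref, rows$alt,
    ".", "PASS", ".", "GT",
    do.call(paste, c(lapply(individuals, function(i) rows[[i]]), sep = "\t")),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a known-SNP catalog (BED or VCF)
#'
#' BED input is 0-based half-open, three columns plus an optional fourth
#' column carrying the allele frequency (`.` for unknown). VCF input takes
#' SNV positions and, when present, the `AF` INFO field. Exact-duplicate
#' intervals are collapsed with a warning.
#'
#' @param path Catalog path (`.bed` or `.vcf`).
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `af`
#'   (`NA` = unknown frequency), of class `snp_catalog`.
#' @export
read_snp_catalog <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))
    out <- tibble(
      chrom = fix$CHROM,
      start = as.integer(fix$POS) - 1L,
      end = as.integer(fix$POS) - 1L + nchar(fix$REF),
      af = af
    )
  } else if (file.size(path) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  af = numeric())
  } else {
    first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE)
    gr <- if (ncol(first) >= 4) {
      rtracklayer::import(path, format = "BED", extraCols = c(af = "character"))
    } else {
      rtracklayer::import(path, format = "BED")
    }
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      af = if (!is.null(gr$af)) suppressWarnings(as.numeric(gr$af)) else NA_real_
    )
  }
  dup <- duplicated(out[, c("chrom", "start", "end")])
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate catalog record(s)", sum(dup)))
    out <- out[!dup, ]
  }
  class(out) <- c("snp_catalog", class(out))
  out
}

#' Write a SNP catalog as BED3 + frequency
#'
#' @param catalog Tibble `chrom`, `start`, `end`, optional `af`.
#' @inheritParams write_cytosine_report
#' @return `path`, invisibly.
#' @export
write_snp_catalog <- function(catalog, path, overwrite = FALSE) {
  check_path_writable(path, overwrite)
  af_vec <- if ("af" %in% names(catalog)) catalog$af else rep(NA_real_, nrow(catalog))
  out <- tibble(
    chrom = catalog$chrom, start = catalog$start, end = catalog$end,
    af = ifelse(is.na(af_vec), ".", as.character(af_vec))
  ) |>
    arrange(.data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Query a catalog for overlap with CpG dyads (or points)
#'
#' @param catalog A catalog tibble from [read_snp_catalog()] (or any tibble
#'   with `chrom`, `start`, `end`).
#' @param chrom,pos Query vectors; the query interval is
#'   `[pos, pos + width)`.
#' @param width Query width: 2 for a CpG dyad (default), 1 for a point.
#' @return Logical vector: does any catalog record overlap each query?
#' @export
catalog_overlaps <- function(catalog, chrom, pos, width = 2) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  if (is.null(catalog) || nrow(catalog) == 0) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = width))
  s <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(start = catalog$start + 1L, end = catalog$end)
  )
  ## different chromosome sets are a legitimate miss, not a warning
  suppressWarnings(GenomicRanges::countOverlaps(q, s) > 0)
}

#' Write a pooled methylation track as bedGraph
#'
#' One dyad per line, 0-based half-open `[pos, pos + 2)`, value = pooled
#' methylation percentage (0-100), matching public track conventions. Input is
#' sorted before writing.
#'
#' @param track Tibble with `chrom`, `pos` and either `percent` (0-100) or
#'   `rate` (0-1).
#' @inheritParams write_cytosine_report
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, overwrite = FALSE) {
  check_path_writable(path, overwrite)
  value <- if ("percent" %in% names(track)) track$percent else {
    if (!"rate" %in% names(track)) abort("track needs a `percent` or `rate` column")
    100 * track$rate
  }
  ord <- order(track$chrom, track$pos)
  gr <- GenomicRanges::GRanges(
    track$chrom[ord],
    IRanges::IRanges(start = track$pos[ord] + 1L, width = 2L),
    score = value[ord]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a dyad-level bedGraph track
#'
#' @param path bedGraph path.
#' @return Tibble `chrom`, `pos` (0-based forward C), `percent`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    percent = gr$score
  )
}

#' Write genotype calls as a single-sample VCF
#'
#' Encodes [call_genotypes()] output at forward-C positions: REF is `C`,
#' ALT lists the called non-reference allele(s), QUAL is the Phred-scaled
#' posterior (`-10 log10(1 - posterior)`, capped at 99), and FILTER carries
#' `PASS` / `LOW_COV` / `AMBIGUOUS`.
#'
#' @param calls Call tibble (`chrom`, `pos`, `genotype`, `posterior`,
#'   `filter`).
#' @param path Output path.
#' @param sample_id Sample column name in the VCF.
#' @inheritParams write_cytosine_report
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(calls, path, sample_id = "SAMPLE",
                            overwrite = FALSE) {
  check_path_writable(path, overwrite)
  al <- gt_alleles(calls$genotype)
  alt_list <- lapply(seq_len(nrow(al)), function(i) {
    setdiff(unique(al[i, ]), "C")
  })
  alt <- vapply(alt_list, function(a) {
    if (length(a) == 0) "." else paste(a, collapse = ",")
  }, character(1))
  gt_code <- vapply(seq_len(nrow(al)), function(i) {
    code <- match(al[i, ], c("C", alt_list[[i]])) - 1L
    paste(sort(code), collapse = "/")
  }, character(1))
  qual <- pmin(99, round(-10 * log10(pmax(1e-10, 1 - calls$posterior)), 1))
  ord <- order(calls$chrom, calls$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=methleakr",
    '##FILTER=<ID=LOW_COV,Description="Total depth below min_depth">',
    '##FILTER=<ID=AMBIGUOUS,Description="Genotype posterior below threshold">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  body <- paste(
    calls$chrom[ord], calls$pos[ord] + 1L, ".", "C", alt[ord], qual[ord],
    calls$filter[ord], ".", "GT", gt_code[ord],
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype calls written by [write_vcf_calls()]
#'
#' @param path VCF path.
#' @return Tibble `chrom`, `pos` (0-based), `genotype`, `posterior`, `filter`.
#' @export
read_vcf_calls <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  alleles <- function(i) {
    all_alleles <- c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    idx <- as.integer(strsplit(gt[i], "/", fixed = TRUE)[[1]]) + 1L
    genotype_string(all_alleles[idx[1]], all_alleles[idx[2]])
  }
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    genotype = vapply(seq_len(nrow(fix)), alleles, character(1)),
    posterior = 1 - 10^(-as.numeric(fix$QUAL) / 10),
    filter = fix$FILTER
  )
}

#' Read / write a sample sheet
#'
#' Tab-separated sheet mapping samples to individuals, tissues and
#' relationship groups.
#'
#' @param path File path.
#' @return Tibble `sample_id`, `individual_id`, `tissue`,
#'   `relationship_group`.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = "cccc", progress = FALSE)
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet tibble.
#' @inheritParams write_cytosine_report
#' @export
write_sample_sheet <- function(samples, path, overwrite = FALSE) {
  check_path_writable(path, overwrite)
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}
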