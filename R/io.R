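# Readers/writers for the plain-text formats the pipeline touches. All BED
# family inputs stay 0-based half-open; 1-based formats (SNP tables, GTF) are
# converted on read and back-converted on write, so write(read(f)) is
# byte-identical on canonical files. Outputs are tab-separated with a single
# "#"-prefixed header line.

FORMATS <- c("bed3", "bed6", "narrowPeak", "bedpe", "gtf_genes",
             "snp_tsv", "motif_bed6")

#' Read a typed record table from one of the supported plain-text formats
#'
#' @param path file path.
#' @param format one of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"bedpe"`,
#'   `"gtf_genes"`, `"snp_tsv"`, `"motif_bed6"`.
#' @param ... passed to the format-specific reader (e.g. `mark`, `cell_line`,
#'   `replicate` for narrowPeak; `dataset`, `q_col` for BEDPE).
#' @return a typed data.frame (or a `gene_models` object for `"gtf_genes"`).
#' @export
read_records <- function(path, format, ...) {
  if (length(format) != 1 || !format %in% FORMATS) {
    stop("unknown format '", paste(format, collapse = ","),
         "'; supported formats: ", paste(FORMATS, collapse = ", "))
  }
  switch(format,
    bed3 = read_bed(path, n_col = 3),
    bed6 = read_bed(path, n_col = 6),
    narrowPeak = read_narrowpeak(path, ...),
    bedpe = read_bedpe(path, ...),
    gtf_genes = read_gtf_genes(path),
    snp_tsv = read_snp_tsv(path),
    motif_bed6 = read_motif_bed(path)
  )
}

# -- line-level plumbing -----------------------------------------------------

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path)
}

split_fields <- function(lines, min_col, path) {
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_col)) {
    bad <- which(nf < min_col)[1]
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, found %d",
                 lineno[bad], path, min_col, nf[bad]))
  }
  list(fields = fields, lineno = lineno)
}

field_num <- function(fx, col, lineno, path) {
  v <- suppressWarnings(as.numeric(vapply(fx$fields, `[[`, "", col)))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop(sprintf("malformed line %d in %s: column %d is not numeric",
                 fx$lineno[bad], path, col))
  }
  v
}

field_chr <- function(fx, col) vapply(fx$fields, `[[`, "", col)

fmt_pos <- function(x) sprintf("%.0f", x)
fmt_num <- function(x) vapply(x, function(v) as.character(v), "")

write_tsv_hash <- function(header, rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(header, collapse = "\t")), con)
  if (length(rows)) writeLines(rows, con)
  invisible(path)
}

# -- BED3 / BED6 -------------------------------------------------------------

#' @rdname read_records
#' @param n_col 3 or 6 BED columns.
#' @export
read_bed <- function(path, n_col = 3) {
  fx <- split_fields(read_lines_checked(path), n_col, path)
  if (length(fx$fields) == 0) {
    out <- genomic_intervals("x", 0, 1)[0, ]
    if (n_col >= 6) { out$name <- character(0); out$score <- numeric(0) }
    return(out)
  }
  strand <- if (n_col >= 6) field_chr(fx, 6) else "*"
  strand[strand == "."] <- "*"   # BED convention for "no strand"
  out <- genomic_intervals(field_chr(fx, 1),
                           field_num(fx, 2, fx$lineno, path),
                           field_num(fx, 3, fx$lineno, path), strand)
  if (n_col >= 6) {
    out$name <- field_chr(fx, 4)
    out$score <- field_num(fx, 5, fx$lineno, path)
    out <- out[, c("chrom", "start", "end", "name", "score", "strand")]
  } else {
    out$strand <- NULL
  }
  out
}

#' Write intervals as BED3 or BED6
#' @param df interval table (`name`, `score`, `strand` columns trigger BED6).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  bed6 <- all(c("name", "score", "strand") %in% names(df))
  if (bed6) {
    rows <- paste(df$chrom, fmt_pos(df$start), fmt_pos(df$end),
                  df$name, fmt_num(df$score), df$strand, sep = "\t")
    write_tsv_hash(c("chrom", "start", "end", "name", "score", "strand"),
                   rows, path)
  } else {
    rows <- paste(df$chrom, fmt_pos(df$start), fmt_pos(df$end), sep = "\t")
    write_tsv_hash(c("chrom", "start", "end"), rows, path)
  }
}

#' Read oriented motif calls (BED6; strand must be + or -)
#' @param path file path.
#' @export
read_motif_bed <- function(path) {
  out <- read_bed(path, n_col = 6)
  if (any(!out$strand %in% c("+", "-"))) {
    stop("motif BED6 requires every record stranded (+ or -): ", path)
  }
  out
}

# -- narrowPeak --------------------------------------------------------------

#' Read ENCODE narrowPeak (BED6+4)
#'
#' Column 10 (summit offset from start) of -1 maps to an absent summit
#' (`NA`). The `mark` / `cell_line` / `replicate` tags are attached to every
#' record so peak sets from many datasets can be concatenated safely.
#'
#' @param path file path.
#' @param mark,cell_line,replicate dataset tags attached to each record.
#' @export
read_narrowpeak <- function(path, mark = NA_character_,
                            cell_line = NA_character_,
                            replicate = NA_character_) {
  fx <- split_fields(read_lines_checked(path), 10, path)
  if (length(fx$fields) == 0) return(empty_peaks(mark, cell_line, replicate))
  summit <- field_num(fx, 10, fx$lineno, path)
  out <- data.frame(
    chrom = field_chr(fx, 1),
    start = field_num(fx, 2, fx$lineno, path),
    end = field_num(fx, 3, fx$lineno, path),
    name = field_chr(fx, 4),
    score = field_num(fx, 5, fx$lineno, path),
    strand = field_chr(fx, 6),
    signal = field_num(fx, 7, fx$lineno, path),
    pvalue = field_num(fx, 8, fx$lineno, path),
    qvalue = field_num(fx, 9, fx$lineno, path),
    summit_offset = ifelse(summit < 0, NA_real_, summit),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.na(out$summit_offset) &
                 (out$summit_offset >= out$end - out$start))
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d in %s: summit offset outside peak",
                 fx$lineno[bad[1]], path))
  }
  out$mark <- mark
  out$cell_line <- cell_line
  out$replicate <- replicate
  out
}

empty_peaks <- function(mark = NA_character_, cell_line = NA_character_,
                        replicate = NA_character_) {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             signal = numeric(0), pvalue = numeric(0), qvalue = numeric(0),
             summit_offset = numeric(0), mark = character(0),
             cell_line = character(0), replicate = character(0),
             stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#' @param df peak table as returned by [read_narrowpeak()].
#' @param path output path.
#' @export
write_narrowpeak <- function(df, path) {
  summit <- ifelse(is.na(df$summit_offset), -1, df$summit_offset)
  rows <- paste(df$chrom, fmt_pos(df$start), fmt_pos(df$end), df$name,
                fmt_num(df$score), df$strand, fmt_num(df$signal),
                fmt_num(df$pvalue), fmt_num(df$qvalue), fmt_pos(summit),
                sep = "\t")
  write_tsv_hash(c("chrom", "start", "end", "name", "score", "strand",
                   "signalValue", "pValue", "qValue", "peak"),
                 if (nrow(df)) rows else character(0), path)
}

# Absolute 0-based summit position; midpoint when the summit is absent.
peak_summits <- function(peaks) {
  mid <- floor((peaks$start + peaks$end) / 2)
  ifelse(is.na(peaks$summit_offset), mid, peaks$start + peaks$summit_offset)
}

# -- BEDPE -------------------------------------------------------------------

#' Read chromatin loops from BEDPE
#'
#' Anchors are canonicalised so `start1 < start2` for intra-chromosomal
#' records (inter-chromosomal records, kept for the filter step to reject and
#' count, are ordered by chromosome name). The loop q-value is taken from
#' `q_col` (column 8, the BEDPE score slot, by default); a missing column
#' yields `NA` q-values, treated as passing by [filter_loops()] with a
#' warning.
#'
#' @param path file path.
#' @param dataset interaction-dataset label attached to every loop.
#' @param q_col 1-based column index holding the loop q-value.
#' @export
read_bedpe <- function(path, dataset = NA_character_, q_col = 8) {
  fx <- split_fields(read_lines_checked(path), min(7, q_col), path)
  if (length(fx$fields) == 0) return(empty_loops(dataset))
  n <- length(fx$fields)
  has_q <- all(lengths(fx$fields) >= q_col)
  out <- data.frame(
    chrom1 = field_chr(fx, 1),
    start1 = field_num(fx, 2, fx$lineno, path),
    end1 = field_num(fx, 3, fx$lineno, path),
    chrom2 = field_chr(fx, 4),
    start2 = field_num(fx, 5, fx$lineno, path),
    end2 = field_num(fx, 6, fx$lineno, path),
    name = if (all(lengths(fx$fields) >= 7)) field_chr(fx, 7) else
      paste0("loop_", seq_len(n)),
    q_value = if (has_q) field_num(fx, q_col, fx$lineno, path) else NA_real_,
    stringsAsFactors = FALSE
  )
  out$dataset <- dataset
  canonicalize_loops(out)
}

empty_loops <- function(dataset = NA_character_) {
  data.frame(chrom1 = character(0), start1 = numeric(0), end1 = numeric(0),
             chrom2 = character(0), start2 = numeric(0), end2 = numeric(0),
             name = character(0), q_value = numeric(0), dataset = character(0),
             stringsAsFactors = FALSE)
}

#' Canonicalise loop anchor order
#'
#' Ensures anchor1 precedes anchor2 (`start1 < start2` on the same
#' chromosome) so anchor-dependent results are invariant to input order.
#'
#' @param loops loop table as from [read_bedpe()].
#' @export
canonicalize_loops <- function(loops) {
  swap <- (loops$chrom1 == loops$chrom2 & loops$start1 > loops$start2) |
    (loops$chrom1 > loops$chrom2)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <-
      loops[swap, c("chrom2", "start2", "end2")]
    loops[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  loops
}

#' Write loops as BEDPE (q-value in column 8)
#' @param loops loop table.
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  rows <- paste(loops$chrom1, fmt_pos(loops$start1), fmt_pos(loops$end1),
                loops$chrom2, fmt_pos(loops$start2), fmt_pos(loops$end2),
                loops$name, fmt_num(loops$q_value), sep = "\t")
  write_tsv_hash(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                   "name", "q_value"),
                 if (nrow(loops)) rows else character(0), path)
}

# -- SNP table ---------------------------------------------------------------

#' Read a fine-mapped SNP table (TSV, 1-based positions)
#'
#' Expects a header line `rsid  chrom  pos` (optionally "#"-prefixed);
#' positions are converted to 0-based `pos0 = pos - 1`.
#'
#' @param path file path.
#' @export
read_snp_tsv <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty SNP table: ", path)
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% header)) {
    stop("SNP table must have header columns rsid, chrom, pos: ", path)
  }
  body <- lines[-1]
  body <- body[!startsWith(body, "#")]
  if (length(body) == 0) {
    return(data.frame(rsid = character(0), chrom = character(0),
                      pos0 = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < length(header))) {
    bad <- which(nf < length(header))[1]
    stop(sprintf("malformed line %d in %s: expected %d fields, found %d",
                 bad + 1, path, length(header), nf[bad]))
  }
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "",
                                            match("pos", header))))
  if (anyNA(pos)) {
    stop(sprintf("malformed line %d in %s: pos is not numeric",
                 which(is.na(pos))[1] + 1, path))
  }
  if (any(pos < 1)) stop("SNP positions are 1-based and must be >= 1: ", path)
  data.frame(rsid = vapply(fields, `[[`, "", match("rsid", header)),
             chrom = vapply(fields, `[[`, "", match("chrom", header)),
             pos0 = pos - 1,
             stringsAsFactors = FALSE)
}

#' Write a SNP table (1-based positions, "#"-prefixed header)
#' @param snps data.frame with `rsid`, `chrom`, `pos0`.
#' @param path output path.
#' @export
write_snp_tsv <- function(snps, path) {
  rows <- paste(snps$rsid, snps$chrom, fmt_pos(snps$pos0 + 1), sep = "\t")
  write_tsv_hash(c("rsid", "chrom", "pos"),
                 if (nrow(snps)) rows else character(0), path)
}

# -- minimal GTF -------------------------------------------------------------

#' Gene models container
#'
#' @param genes data.frame with `gene_id`, `gene_name`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open span), `tss_pos0`,
#'   `tes_pos0` (TSS/TES respect strand: the TSS is the 5' end).
#' @param exons data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(genes$strand %in% c("+", "-")))
  if (nrow(exons) > 0) {
    i <- match(exons$gene_id, genes$gene_id)
    if (anyNA(i)) stop("exon references unknown gene_id")
    if (any(exons$start < genes$start[i]) || any(exons$end > genes$end[i])) {
      stop("exon outside gene span")
    }
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read gene models from a minimal Gencode-style GTF
#'
#' Uses `gene` rows for spans/strand and `exon` rows for exon structure;
#' 1-based closed GTF coordinates are converted to 0-based half-open.
#'
#' @param path file path.
#' @export
read_gtf_genes <- function(path) {
  fx <- split_fields(read_lines_checked(path), 9, path)
  feat <- field_chr(fx, 3)
  attr_field <- field_chr(fx, 9)
  get_attr <- function(key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, attr_field)
    out <- rep(NA_character_, length(attr_field))
    out[m > 0] <- sub(pat, "\\1", regmatches(attr_field, m))
    out
  }
  gid <- get_attr("gene_id")
  gname <- get_attr("gene_name")
  start <- field_num(fx, 4, fx$lineno, path) - 1
  end <- field_num(fx, 5, fx$lineno, path)
  strand <- field_chr(fx, 7)
  g <- feat == "gene"
  if (!any(g)) stop("no 'gene' features found in ", path)
  genes <- data.frame(gene_id = gid[g], gene_name = gname[g],
                      chrom = field_chr(fx, 1)[g], strand = strand[g],
                      start = start[g], end = end[g],
                      stringsAsFactors = FALSE)
  genes$tss_pos0 <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tes_pos0 <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  e <- feat == "exon"
  exons <- data.frame(gene_id = gid[e], chrom = field_chr(fx, 1)[e],
                      start = start[e], end = end[e],
                      stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

#' Write gene models as minimal GTF
#' @param gm `gene_models` object.
#' @param path output path.
#' @export
write_gtf_genes <- function(gm, path) {
  g <- gm$genes
  attr_g <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$gene_name)
  gene_rows <- paste(g$chrom, "riskloop", "gene", fmt_pos(g$start + 1),
                     fmt_pos(g$end), ".", g$strand, ".", attr_g, sep = "\t")
  e <- gm$exons
  rows <- gene_rows
  if (nrow(e) > 0) {
    i <- match(e$gene_id, g$gene_id)
    attr_e <- sprintf('gene_id "%s"; gene_name "%s";',
                      e$gene_id, g$gene_name[i])
    exon_rows <- paste(e$chrom, "riskloop", "exon", fmt_pos(e$start + 1),
                       fmt_pos(e$end), ".", g$strand[i], ".", attr_e,
                       sep = "\t")
    # keep exons grouped after their gene, in gene order
    rows <- unlist(lapply(seq_len(nrow(g)), function(k) {
      c(gene_rows[k], exon_rows[i == k])
    }))
  }
  write_tsv_hash(c("seqname", "source", "feature", "start", "end", "score",
                   "strand", "frame", "attributes"), rows, path)
}
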