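#' @importFrom stats cor cov cutree dist dnorm hclust kmeans mad median
#'   p.adjust phyper pnorm quantile rbinom rlnorm rnbinom rnorm runif sd
#'   setNames var rpois prcomp uniroot
#' @importFrom utils head read.delim write.table
NULL

# ---- CountTable ----------------------------------------------------------

#' Construct a validated count table
#'
#' A `CountTable` is an integer matrix of read counts with genes as rows and
#' samples as columns, the container used by all expression stages.
#'
#' @param counts numeric matrix of non-negative integers, with rownames
#'   (gene ids) and colnames (sample ids).
#' @return an object of class `CountTable` (an integer matrix).
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table needs at least 1 gene and 1 sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table requires gene rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("CountTable", class(counts))
  counts
}

#' Read a count table from TSV
#'
#' First column gene ids, header row sample ids, integer cells.
#'
#' @param path path to a tab-separated file.
#' @return a [count_table()].
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count TSV needs a gene-id column plus >=1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cell found")
  rownames(m) <- ids
  count_table(m)
}

#' Write a count table to TSV
#' @param x a `CountTable`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- SampleDesign --------------------------------------------------------

#' Construct a sample design table
#'
#' Maps each sample to a root developmental zone (MZ = meristematic,
#' EZ = elongation, DZ = differentiation) and replicate number.
#'
#' @param sample_id character vector.
#' @param zone character vector over \{"MZ","EZ","DZ"\}.
#' @param replicate positive integer vector.
#' @return a `data.frame` of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, zone, replicate) {
  zone <- as.character(zone)
  if (!all(zone %in% c("MZ", "EZ", "DZ")))
    stop("zone must be one of MZ, EZ, DZ")
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate must be a positive integer")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in design")
  out <- data.frame(sample_id = as.character(sample_id), zone = zone,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("SampleDesign", class(out))
  out
}

check_design <- function(counts, design) {
  if (!setequal(colnames(counts), design$sample_id) ||
      ncol(counts) != nrow(design))
    stop("design rows must match count table samples exactly")
  design[match(colnames(counts), design$sample_id), , drop = FALSE]
}

# ---- FASTA ---------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; IUPAC ambiguity codes are preserved.
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record(s): ",
                                   paste(ids[nchar(seqs) == 0L], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- PWM -----------------------------------------------------------------

#' Construct a position weight matrix record
#'
#' Columns are normalized to relative base frequencies; a pseudocount of 0.01
#' is added before normalization only when a zero entry exists, so clean
#' matrices are untouched but log-odds never hit minus infinity.
#'
#' @param motif_id motif identifier.
#' @param regulator_id the transcription factor this motif belongs to.
#' @param matrix 4 x L numeric matrix, rows in A,C,G,T order.
#' @return an object of class `PWMRecord` with elements `motif_id`,
#'   `regulator_id`, `matrix`.
#' @export
pwm_record <- function(motif_id, regulator_id, matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L) stop("PWM must have 4 rows (A,C,G,T)")
  if (ncol(m) < 4L) stop("PWM width must be >= 4")
  if (any(!is.finite(m)) || any(m < 0)) stop("PWM entries must be finite and >= 0")
  if (any(colSums(m) == 0)) stop("PWM has an all-zero column")
  if (any(m == 0)) m <- m + 0.01
  m <- sweep(m, 2L, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, regulator_id = regulator_id, matrix = m),
            class = "PWMRecord")
}

#' Read a PWM from a CisBP-style tab file or MEME minimal format
#'
#' CisBP files are tab-separated with a header containing A/C/G/T columns and
#' one row per motif position. MEME minimal files are parsed at their
#' "letter-probability matrix" block (rows are positions, columns A,C,G,T).
#'
#' @param path motif file path.
#' @param regulator_id regulator to attach; defaults to the motif id.
#' @return a [pwm_record()].
#' @export
read_pwm <- function(path, regulator_id = NULL) {
  lines <- readLines(path)
  if (any(grepl("^MEME version", lines))) {
    i <- grep("^letter-probability matrix", lines)
    if (!length(i)) stop("MEME file lacks a letter-probability matrix block")
    mline <- grep("^MOTIF", lines, value = TRUE)
    motif_id <- if (length(mline)) strsplit(trimws(mline[1L]), "\\s+")[[1L]][2L] else "motif"
    rows <- list()
    j <- i[1L] + 1L
    while (j <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[j])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1L]])
      j <- j + 1L
    }
    m <- t(do.call(rbind, rows))
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    cols <- toupper(names(df))
    need <- c("A", "C", "G", "T")
    if (!all(need %in% cols)) stop("CisBP PWM needs A/C/G/T columns")
    m <- t(as.matrix(df[, match(need, cols), drop = FALSE]))
    motif_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pwm_record(motif_id, regulator_id %||% motif_id, m)
}

#' Write a PWM in CisBP-style tab format
#' @param pwm a `PWMRecord`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(Pos = seq_len(ncol(pwm$matrix)), t(pwm$matrix),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus string of a PWM (argmax base per column)
#' @param pwm a `PWMRecord`.
#' @return a character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2L, which.max)], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- AnnotationTable -----------------------------------------------------

#' Construct a gene annotation table
#'
#' Coordinates are 1-based inclusive throughout the package. The TSS is
#' `span_start` on the + strand and `span_end` on the - strand.
#'
#' @param gene_id,chrom character vectors.
#' @param strand "+" or "-".
#' @param span_start,span_end 1-based inclusive gene extent.
#' @return a `data.frame` of class `AnnotationTable` with a derived `tss`.
#' @export
annotation_table <- function(gene_id, chrom, strand, span_start, span_end) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("unknown strand value")
  span_start <- as.integer(span_start); span_end <- as.integer(span_end)
  if (any(span_start > span_end)) stop("span_start > span_end")
  if (any(span_start < 1L)) stop("coordinates must be 1-based positive")
  if (anyDuplicated(gene_id)) stop("duplicate gene ids in annotation")
  out <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    strand = strand, tss = ifelse(strand == "+", span_start, span_end),
                    span_start = span_start, span_end = span_end,
                    stringsAsFactors = FALSE)
  class(out) <- c("AnnotationTable", class(out))
  out
}

#' Read gene annotation from BED6 or GFF3
#'
#' BED intervals (0-based half-open) are converted to the package's 1-based
#' inclusive convention on read; GFF3 `gene` lines are taken as is.
#'
#' @param path annotation path; the dialect is sniffed from content
#'   (`##gff` header or 9-column tab lines mean GFF3).
#' @return an [annotation_table()].
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no annotation records in ", path)
  fields <- strsplit(body, "\t")
  nf <- lengths(fields)
  is_gff <- any(startsWith(lines, "##gff")) || all(nf == 9L)
  if (is_gff) {
    keep <- vapply(fields, function(f) f[3L] %in% c("gene", "Gene"), logical(1L))
    fields <- fields[keep]
    if (!length(fields)) stop("no gene features in GFF3")
    ids <- vapply(fields, function(f) {
      m <- regmatches(f[9L], regexec("ID=([^;]+)", f[9L]))[[1L]]
      if (length(m) == 2L) m[2L] else f[9L]
    }, character(1L))
    annotation_table(
      gene_id = ids,
      chrom = vapply(fields, `[`, character(1L), 1L),
      strand = vapply(fields, `[`, character(1L), 7L),
      span_start = as.integer(vapply(fields, `[`, character(1L), 4L)),
      span_end = as.integer(vapply(fields, `[`, character(1L), 5L)))
  } else {
    if (any(nf < 6L)) stop("BED6 requires 6 fields")
    annotation_table(
      gene_id = vapply(fields, `[`, character(1L), 4L),
      chrom = vapply(fields, `[`, character(1L), 1L),
      strand = vapply(fields, `[`, character(1L), 6L),
      span_start = as.integer(vapply(fields, `[`, character(1L), 2L)) + 1L,
      span_end = as.integer(vapply(fields, `[`, character(1L), 3L)))
  }
}

#' Write annotation as GFF3 gene lines or BED6
#' @param ann an `AnnotationTable`.
#' @param path output path.
#' @param format "gff3" or "bed".
#' @return invisibly, `path`.
#' @export
write_annotation <- function(ann, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tramnet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       ann$chrom, ann$span_start, ann$span_end, ann$strand,
                       ann$gene_id))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t.\t%s", ann$chrom, ann$span_start - 1L,
                     ann$span_end, ann$gene_id, ann$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- GMT gene sets -------------------------------------------------------

#' Read a GMT gene-set file
#' @param path GMT path (term, description, members...).
#' @return a named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 3L)) stop("GMT line with fewer than 3 fields")
  terms <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(terms)) stop("duplicate GMT term ids")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- terms
  attr(sets, "description") <- setNames(vapply(fields, `[`, character(1L), 2L), terms)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "description") %||%
    setNames(rep(".", length(sets)), names(sets))
  lines <- vapply(names(sets), function(t)
    paste(c(t, desc[[t]] %||% ".", sets[[t]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- Edge lists ----------------------------------------------------------

#' Construct a validated undirected edge list
#'
#' @param node_a,node_b character endpoint vectors.
#' @param weight optional numeric weights (NA allowed).
#' @param evidence optional free-text evidence tags.
#' @return a `data.frame` of class `EdgeList`, with canonical unordered keys.
#' @export
edge_list <- function(node_a, node_b, weight = NA_real_, evidence = "") {
  node_a <- as.character(node_a); node_b <- as.character(node_b)
  if (any(node_a == node_b)) stop("self-edges are not allowed")
  if (any(!is.na(weight) & !is.finite(weight))) stop("weights must be finite or NA")
  key <- ifelse(node_a < node_b, paste(node_a, node_b, sep = "|"),
                paste(node_b, node_a, sep = "|"))
  if (anyDuplicated(key)) stop("duplicate unordered edge(s)")
  out <- data.frame(node_a = node_a, node_b = node_b,
                    weight = rep_len(as.numeric(weight), length(node_a)),
                    evidence = rep_len(as.character(evidence), length(node_a)),
                    edge_id = key, stringsAsFactors = FALSE)
  class(out) <- c("EdgeList", class(out))
  out
}

#' Read an edge list from TSV
#' @param path TSV with columns node_a, node_b and optional weight, evidence.
#' @return an [edge_list()].
#' @export
read_edges <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  edge_list(df$node_a, df$node_b,
            weight = if ("weight" %in% names(df)) df$weight else NA_real_,
            evidence = if ("evidence" %in% names(df)) df$evidence else "")
}

#' Write an edge list to TSV
#' @param edges an `EdgeList`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edges <- function(edges, path) {
  write.table(edges[, c("node_a", "node_b", "weight", "evidence")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
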