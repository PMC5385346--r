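# Domain types and readers: gene annotation, FPKM expression matrix, sample
# sheet, dataset validation, and transcriptome-level QC (replicate
# concordance, housekeeping variability, sex-marker verification).

SEXES    <- c("male", "female")
GROUPS   <- c("IVF", "SCNT", "SHAM", "DONOR")
LINEAGES <- c("WHOLE", "IT", "TE")

DEFAULT_PAR_SYMBOLS <- c("ZBED1", "CD99")
DEFAULT_HOUSEKEEPING_SYMBOLS <- c("GAPDH", "ACTB", "B2M", "PPIA", "TBP",
                                  "HMBS", "YWHAZ", "SDHA", "UBC", "RPL13A")
DEFAULT_FEMALE_MARKERS <- "XIST"
DEFAULT_MALE_MARKERS   <- c("UTY", "DDX3Y", "EIF2S3Y")

strip_chr <- function(chrom) sub("^chr", "", as.character(chrom))

#' Classify a chromosome name
#'
#' Pure function of the chromosome name: numeric names are autosomal, X/Y are
#' the sex chromosomes, MT/M is mitochondrial, and everything else (unplaced
#' scaffolds) is `unmapped`. Unmapped genes are retained for transcriptome-wide
#' QC but excluded from chromosome-level statistics.
#'
#' @param chrom character vector of chromosome names (with or without a
#'   `chr` prefix)
#' @return character vector over
#'   `{autosomal, x_linked, y_linked, mito, unmapped}`
#' @export
chrom_class_of <- function(chrom) {
  ch <- strip_chr(chrom)
  out <- rep("unmapped", length(ch))
  out[grepl("^[0-9]+$", ch)] <- "autosomal"
  out[ch %in% c("X", "x")] <- "x_linked"
  out[ch %in% c("Y", "y")] <- "y_linked"
  out[ch %in% c("MT", "M", "Mt")] <- "mito"
  out
}

finish_annotation <- function(ann, par_symbols, testes_symbols, housekeeping_symbols) {
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in annotation: ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(ann$end_bp < ann$start_bp)
  if (length(bad)) {
    stop("end < start for gene(s): ", paste(ann$gene_id[bad], collapse = ", "))
  }
  ann$chrom <- strip_chr(ann$chrom)
  ann$strand <- ifelse(ann$strand %in% c("+", "-"), ann$strand, "unknown")
  ann$chrom_class <- chrom_class_of(ann$chrom)
  ann$is_unmapped <- ann$chrom_class == "unmapped"
  ann$is_par <- ann$symbol %in% par_symbols & ann$chrom %in% c("X", "Y")
  ann$is_xist <- ann$symbol == "XIST"
  ann$is_testes_specific <- ann$symbol %in% (testes_symbols %||% character())
  ann$is_housekeeping <- ann$symbol %in% (housekeeping_symbols %||% character())
  rownames(ann) <- NULL
  ann
}

#' Load a gene annotation table
#'
#' Accepts either a tab-delimited table with columns
#' `gene_id, symbol, chrom, start, end, strand` (or `start_bp`/`end_bp`), or a
#' GTF/GFF file, in which case feature rows are reduced to one record per
#' `gene_id` spanning `min(start)..max(end)`. Coordinates are 1-based
#' inclusive on input.
#'
#' @param path annotation file (TSV or `.gtf`/`.gff`)
#' @param par_symbols symbols treated as pseudoautosomal when on X or Y
#' @param testes_symbols optional symbols of a curated testes-specific set
#' @param housekeeping_symbols symbols flagged as housekeeping genes
#' @return data.frame with one row per gene and derived columns
#'   `chrom_class`, `is_unmapped`, `is_par`, `is_xist`, `is_testes_specific`,
#'   `is_housekeeping`
#' @export
load_annotation <- function(path,
                            par_symbols = DEFAULT_PAR_SYMBOLS,
                            testes_symbols = NULL,
                            housekeeping_symbols = DEFAULT_HOUSEKEEPING_SYMBOLS) {
  if (grepl("\\.(gtf|gff3?)(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF/GFF annotation requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    if (is.null(md$gene_id)) stop("GTF/GFF lacks a gene_id attribute")
    sym <- if (!is.null(md$gene_name)) md$gene_name else md$gene_id
    sym[is.na(sym)] <- md$gene_id[is.na(sym)]
    ids <- unique(md$gene_id)
    idx <- split(seq_len(nrow(md)), md$gene_id)[ids]
    ann <- data.frame(
      gene_id = ids,
      symbol = vapply(idx, function(i) sym[i[1]], ""),
      chrom = vapply(idx, function(i) as.character(md$seqnames[i[1]]), ""),
      start_bp = vapply(idx, function(i) min(md$start[i]), 0),
      end_bp = vapply(idx, function(i) max(md$end[i]), 0),
      strand = vapply(idx, function(i) {
        s <- unique(as.character(md$strand[i]))
        if (length(s) == 1L && s %in% c("+", "-")) s else "unknown"
      }, ""),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- read_xdg_tsv(path)
    names(raw) <- sub("^start$", "start_bp", sub("^end$", "end_bp", names(raw)))
    need <- c("gene_id", "symbol", "chrom", "start_bp", "end_bp", "strand")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
    ann <- raw[, need]
    ann$gene_id <- as.character(ann$gene_id)
    ann$symbol <- as.character(ann$symbol)
  }
  ann$start_bp <- as.integer(ann$start_bp)
  ann$end_bp <- as.integer(ann$end_bp)
  finish_annotation(ann, par_symbols, testes_symbols, housekeeping_symbols)
}

#' Load a genes-by-samples FPKM matrix
#'
#' Tab-delimited, first column gene ids, header row sample ids, numeric
#' non-negative body. Duplicated gene or sample labels, negative values and
#' non-numeric cells are hard errors.
#'
#' @param path TSV file
#' @return numeric matrix with gene ids as rownames, sample ids as colnames
#' @export
load_expression <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression table needs a gene id column and >=1 sample")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicated gene id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    ij <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
    if (nrow(ij)) {
      stop(sprintf("non-numeric cell at gene '%s', sample '%s' (value '%s')",
                   ids[ij[1, 1]], samples[ij[1, 2]], body[ij[1, 1], ij[1, 2]]))
    }
    stop("missing value(s) in expression matrix")
  }
  if (any(vals < 0)) {
    ij <- which(vals < 0, arr.ind = TRUE)
    stop(sprintf("negative FPKM at gene '%s', sample '%s'",
                 ids[ij[1, 1]], samples[ij[1, 2]]))
  }
  dimnames(vals) <- list(ids, samples)
  vals
}

#' Write an FPKM matrix as TSV (round-trips through [load_expression()])
#' @param mat numeric genes-by-samples matrix with dimnames
#' @param path output path
#' @param params named list recorded in the comment header
#' @export
write_expression <- function(mat, path, params = list()) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_xdg_tsv(df, path, params)
}

#' Load a sample sheet
#'
#' Tab-delimited with columns `sample_id, sex, group` and optional
#' `lineage, embryo_id`. Enumerations are case-insensitive; a missing lineage
#' column defaults every sample to `WHOLE`. Dissected samples (`IT`/`TE`)
#' must carry an embryo id, with at most one IT and one TE part per embryo.
#'
#' @param path TSV file
#' @return validated data.frame
#' @export
load_samples <- function(path) {
  raw <- read_xdg_tsv(path)
  need <- c("sample_id", "sex", "group")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  s <- data.frame(
    sample_id = as.character(raw$sample_id),
    sex = tolower(as.character(raw$sex)),
    group = toupper(as.character(raw$group)),
    lineage = if (is.null(raw$lineage)) "WHOLE" else toupper(as.character(raw$lineage)),
    embryo_id = if (is.null(raw$embryo_id)) "" else as.character(raw$embryo_id),
    stringsAsFactors = FALSE
  )
  s$embryo_id[is.na(s$embryo_id)] <- ""
  validate_samples(s)
}

validate_samples <- function(s) {
  if (anyDuplicated(s$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  }
  check_enum <- function(v, allowed, what) {
    bad <- setdiff(unique(v), allowed)
    if (length(bad)) {
      stop(sprintf("unknown %s value(s) %s; allowed: %s", what,
                   paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
    }
  }
  check_enum(s$sex, SEXES, "sex")
  check_enum(s$group, GROUPS, "group")
  check_enum(s$lineage, LINEAGES, "lineage")
  split_part <- s$lineage %in% c("IT", "TE")
  if (any(split_part & s$embryo_id == "")) {
    stop("IT/TE sample(s) without embryo_id: ",
         paste(s$sample_id[split_part & s$embryo_id == ""], collapse = ", "))
  }
  for (ln in c("IT", "TE")) {
    tab <- table(s$embryo_id[s$lineage == ln])
    if (any(tab > 1L)) {
      stop("embryo with more than one ", ln, " part: ",
           paste(names(tab)[tab > 1L], collapse = ", "))
    }
  }
  rownames(s) <- NULL
  s
}

#' Count samples per (sex, group) cell
#' @param samples sample sheet data.frame
#' @return table of counts
#' @export
sample_counts <- function(samples) table(sex = samples$sex, group = samples$group)

#' Assemble a validated dataset from annotation, matrix and sample sheet
#'
#' Intersects genes and samples across the three inputs, orders them
#' consistently, and reports dropped identifiers. Validation is idempotent:
#' re-validating the parts of a validated dataset returns identical content.
#'
#' @param annotation gene table from [load_annotation()]
#' @param matrix FPKM matrix from [load_expression()]
#' @param samples sample sheet from [load_samples()]
#' @return object of class `xdg_dataset`: list with elements `annotation`,
#'   `matrix`, `samples`
#' @export
validate_dataset <- function(annotation, matrix, samples) {
  samples <- validate_samples(samples)
  genes <- intersect(rownames(matrix), annotation$gene_id)
  if (!length(genes)) stop("no genes shared between matrix and annotation")
  smp <- intersect(colnames(matrix), samples$sample_id)
  if (!length(smp)) stop("no samples shared between matrix and sample sheet")
  n_drop_g <- length(union(rownames(matrix), annotation$gene_id)) - length(genes)
  n_drop_s <- length(union(colnames(matrix), samples$sample_id)) - length(smp)
  if (n_drop_g > 0) warning(n_drop_g, " gene id(s) not shared by matrix and annotation were dropped")
  if (n_drop_s > 0) warning(n_drop_s, " sample id(s) not shared by matrix and sample sheet were dropped")
  ann <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  s <- samples[match(smp, samples$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  m <- matrix[genes, smp, drop = FALSE]
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (!any(ann$chrom_class == "autosomal") || !any(ann$chrom_class == "x_linked")) {
    stop("dataset needs at least one autosomal and one X-linked gene")
  }
  structure(list(annotation = ann, matrix = m, samples = s),
            class = "xdg_dataset")
}

#' @export
print.xdg_dataset <- function(x, ...) {
  cat(sprintf("xdg_dataset: %d genes x %d samples (%d X-linked, %d autosomal)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$annotation$chrom_class == "x_linked"),
              sum(x$annotation$chrom_class == "autosomal")))
  print(sample_counts(x$samples))
  invisible(x)
}

# ---- QC --------------------------------------------------------------------

#' Sample-sample Pearson correlation on log-transformed FPKM
#'
#' Replicate-concordance QC. Correlations are computed on
#' `log2(FPKM + pseudocount)` by default. The result is symmetric with a unit
#' diagonal; a zero-variance sample yields missing off-diagonal entries
#' rather than an error.
#'
#' @param x `xdg_dataset` or genes-by-samples matrix (>= 2 samples)
#' @param log_transform log-transform before correlating?
#' @param pseudocount added before the log
#' @return samples-by-samples correlation matrix
#' @export
sample_correlation <- function(x, log_transform = TRUE, pseudocount = 1) {
  m <- if (inherits(x, "xdg_dataset")) x$matrix else x
  if (ncol(m) < 2L) stop("need at least two samples")
  if (log_transform) m <- log2(m + pseudocount)
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}

#' Coefficient of variation of housekeeping genes per sample group
#'
#' For each gene in the list and each (sex, group, lineage) cell, reports
#' `CV = sd/mean` of FPKM across the samples of that cell. A zero mean gives
#' a missing CV. Technical replicates are expected to show markedly lower CV
#' than independent embryos.
#'
#' @param dataset `xdg_dataset`
#' @param genes gene symbols or ids; default: genes flagged `is_housekeeping`
#' @return long data.frame `gene_id, symbol, cell, cv`
#' @export
housekeeping_variability <- function(dataset, genes = NULL) {
  ann <- dataset$annotation
  if (is.null(genes)) {
    keep <- ann$is_housekeeping
  } else {
    keep <- ann$symbol %in% genes | ann$gene_id %in% genes
  }
  if (!any(keep)) stop("none of the requested genes are in the dataset")
  ids <- ann$gene_id[keep]
  cell <- interaction(dataset$samples$sex, dataset$samples$group,
                      dataset$samples$lineage, drop = TRUE, sep = ".")
  out <- expand.grid(gene_id = ids, cell = levels(cell),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$symbol <- ann$symbol[match(out$gene_id, ann$gene_id)]
  out$cv <- mapply(function(g, cl) {
    v <- dataset$matrix[g, cell == cl]
    m <- mean(v)
    if (m == 0) NA_real_ else stats::sd(v) / m
  }, out$gene_id, out$cell)
  out[, c("gene_id", "symbol", "cell", "cv")]
}

#' Predict sample sex from marker expression and check concordance
#'
#' A sample is called female when a female marker (XIST by default) is at or
#' above `min_fpkm` and all male markers (UTY, DDX3Y, EIF2S3Y) are below it;
#' male in the converse situation; otherwise ambiguous. Ambiguity is a value,
#' not an error.
#'
#' @param dataset `xdg_dataset`
#' @param female_markers,male_markers marker gene symbols
#' @param min_fpkm detection threshold
#' @return data.frame `sample_id, annotated_sex, predicted_sex, concordant`
#' @export
verify_sex_markers <- function(dataset,
                               female_markers = DEFAULT_FEMALE_MARKERS,
                               male_markers = DEFAULT_MALE_MARKERS,
                               min_fpkm = 1) {
  ann <- dataset$annotation
  f_ids <- ann$gene_id[ann$symbol %in% female_markers]
  m_ids <- ann$gene_id[ann$symbol %in% male_markers]
  if (!length(f_ids) && !length(m_ids)) stop("no sex-marker genes present in dataset")
  f_on <- if (length(f_ids)) {
    apply(dataset$matrix[f_ids, , drop = FALSE] >= min_fpkm, 2, any)
  } else rep(FALSE, ncol(dataset$matrix))
  m_on <- if (length(m_ids)) {
    apply(dataset$matrix[m_ids, , drop = FALSE] >= min_fpkm, 2, any)
  } else rep(FALSE, ncol(dataset$matrix))
  pred <- ifelse(f_on & !m_on, "female", ifelse(m_on & !f_on, "male", "ambiguous"))
  out <- data.frame(
    sample_id = colnames(dataset$matrix),
    annotated_sex = dataset$samples$sex[match(colnames(dataset$matrix),
                                              dataset$samples$sample_id)],
    predicted_sex = unname(pred),
    stringsAsFactors = FALSE
  )
  out$concordant <- out$predicted_sex == out$annotated_sex
  out
}
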