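## Readers and writers for the plain-text formats the pipeline exchanges.
## BED and bedGraph go through rtracklayer; coordinates are preserved
## bit-exactly (BED is 0-based half-open on disk, GRanges 1-based closed
## in memory).

#' Read a BED3/BED6 file as a GRanges
#' @param path file path.
#' @param genome optional named chromosome lengths to attach and validate.
#' @return `GRanges` sorted by (chrom, start).
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::strand(gr) <- "*"
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- union(names(genome), GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr)[names(genome)] <- genome
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#' @param gr `GRanges`; metadata column `name`/`score` exported when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a two-column chrom.sizes file as a genome
#' @param path TSV with chromosome name and length.
#' @return Named numeric vector (see [genome_sizes()]).
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_sizes(stats::setNames(df$length, df$chrom))
}

#' Read TSS annotation from BED6 or TSV
#'
#' BED6 input uses the interval start (strand +) or end - 1 (strand -) as
#' the TSS point; a TSV must carry columns gene_id, chrom, position,
#' strand with `position` 0-based.
#'
#' @param path file path.
#' @return `data.frame` with columns `gene_id`, `chrom`, `position`, `strand`.
#' @export
read_tss <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    return(df[, c("gene_id", "chrom", "position", "strand")])
  }
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  pos1 <- ifelse(strand == "-", GenomicRanges::end(gr), GenomicRanges::start(gr))
  data.frame(gene_id = if (!is.null(gr$name)) gr$name else as.character(seq_along(gr)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             position = pos1 - 1L, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a differential-expression table
#' @param path TSV with columns `gene_id`, `log2FC`, `fdr` (extra columns
#'   kept); a logical `detected` column is added if absent (TRUE where
#'   log2FC and fdr are non-missing).
#' @return `data.frame`.
#' @export
read_dge_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("gene_id", "log2FC", "fdr")
  if (!all(req %in% names(df))) stop("DGE table must have columns gene_id, log2FC, fdr")
  if (!"detected" %in% names(df))
    df$detected <- stats::complete.cases(df[, c("log2FC", "fdr")])
  df
}

#' Read a bedGraph into a binned track
#'
#' bedGraph values are length-weighted-averaged into fixed-width bins.
#'
#' @param path bedGraph file.
#' @param genome named chromosome lengths.
#' @param feature,condition track labels.
#' @param bin_size bin width in bp (default 200).
#' @return A [binned_track()].
#' @export
read_bedgraph_track <- function(path, genome, feature, condition, bin_size = 200) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(names(genome), function(chr) {
    nb <- ceiling(genome[[chr]] / bin_size)
    acc <- numeric(nb)
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
    if (length(sel) > 0L) {
      s0 <- GenomicRanges::start(sel) - 1L
      e0 <- GenomicRanges::end(sel)
      v <- sel$score
      for (i in seq_along(sel)) {
        b1 <- s0[i] %/% bin_size; b2 <- (e0[i] - 1L) %/% bin_size
        for (b in b1:b2) {
          lo <- max(s0[i], b * bin_size); hi <- min(e0[i], (b + 1L) * bin_size)
          acc[b + 1L] <- acc[b + 1L] + v[i] * (hi - lo)
        }
      }
      acc <- acc / bin_size
    }
    acc
  })
  names(values) <- names(genome)
  binned_track(values, feature = feature, condition = condition, bin_size = bin_size)
}

#' Write binary calls in the binarized-track dialect
#'
#' Per chromosome: a header line `<condition>\t<chrom>`, a line with the
#' feature name, then one 0/1 value per bin.
#'
#' @param calls a [binary_calls()] object.
#' @param dir output directory; one file per chromosome named
#'   `<condition>_<chrom>_binary.txt`.
#' @return Invisible vector of file paths.
#' @export
write_binary_calls <- function(calls, dir) {
  stopifnot(inherits(calls, "binary_calls"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (chr in names(calls$calls)) {
    path <- file.path(dir, paste0(calls$condition, "_", chr, "_binary.txt"))
    con <- file(path, "w")
    writeLines(paste(calls$condition, chr, sep = "\t"), con)
    writeLines(calls$feature, con)
    writeLines(as.character(as.integer(calls$calls[[chr]])), con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read binary calls written by [write_binary_calls()]
#' @param paths files, one per chromosome.
#' @param bin_size bin width in bp.
#' @return A [binary_calls()] object.
#' @export
read_binary_calls <- function(paths, bin_size = 200) {
  calls <- list(); feature <- condition <- NULL
  for (path in paths) {
    lines <- readLines(path)
    hdr <- strsplit(lines[1], "\t")[[1]]
    condition <- hdr[1]; chr <- hdr[2]; feature <- lines[2]
    calls[[chr]] <- as.integer(lines[-(1:2)]) > 0L
  }
  binary_calls(calls, feature = feature, condition = condition, bin_size = bin_size)
}

#' Write a fitted chromatin-state model as JSON
#' @param model an `emission_model` (see [fit_hmm()]).
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(K = model$K, F = model$F,
              feature_names = model$feature_names,
              bin_size = model$bin_size,
              E = model$E, A = model$A, pi = model$pi,
              loglik = model$loglik, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a chromatin-state model JSON
#' @param path JSON written by [write_model_json()].
#' @return An `emission_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  emission_model(E = matrix(obj$E, nrow = obj$K, byrow = FALSE),
                 A = matrix(obj$A, nrow = obj$K, byrow = FALSE),
                 pi = obj$pi, feature_names = obj$feature_names,
                 bin_size = obj$bin_size, loglik = obj$loglik, seed = obj$seed)
}

#' Write a segmentation as dense-segment BED
#'
#' Consecutive bins sharing a state become one BED interval with the state
#' label in the name column (`E<k>`).
#'
#' @param seg a segmentation (see [decode_states()]).
#' @param condition which condition to export.
#' @param path output path.
#' @export
write_segmentation_bed <- function(seg, condition, path) {
  labels <- seg$states[[condition]]
  bin <- seg$bin_size
  rows <- list()
  for (chr in names(labels)) {
    v <- labels[[chr]]
    r <- rle(v)
    e <- cumsum(r$lengths); s <- c(0L, e[-length(e)])
    rows[[chr]] <- data.frame(chrom = chr,
                              start = format(s * bin, scientific = FALSE, trim = TRUE),
                              end = format(e * bin, scientific = FALSE, trim = TRUE),
                              name = paste0("E", r$values))
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a factor peak catalog from a directory of BED files
#' @param dir directory; each `*.bed` file is one factor, named by file stem.
#' @param genome optional genome for validation.
#' @return Named list of flattened `GRanges`.
#' @export
read_factor_catalog <- function(dir, genome = NULL) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (length(files) == 0L) stop("no BED files in catalog directory: ", dir)
  catalog <- lapply(files, function(f) flatten_intervals(read_bed(f, genome)))
  names(catalog) <- sub("\\.bed$", "", basename(files))
  catalog
}

#' Read a region count matrix (regions BED + counts TSV)
#'
#' The TSV has a header row of sample names, a second header row of
#' condition labels (line starting `#condition`), a third line
#' `#lib_size` with per-sample library sizes, then one row of counts per
#' region in BED order.
#'
#' @param bed_path regions BED.
#' @param counts_path counts TSV as described.
#' @return A [region_count_matrix()].
#' @export
read_region_counts <- function(bed_path, counts_path) {
  regions <- read_bed(bed_path)
  lines <- readLines(counts_path)
  samples <- strsplit(lines[1], "\t")[[1]]
  cond <- strsplit(lines[2], "\t")[[1]]; stopifnot(cond[1] == "#condition")
  libs <- strsplit(lines[3], "\t")[[1]]; stopifnot(libs[1] == "#lib_size")
  counts <- do.call(rbind, lapply(lines[-(1:3)], function(l) as.numeric(strsplit(l, "\t")[[1]])))
  colnames(counts) <- samples
  region_count_matrix(regions, counts,
                      condition = cond[-1],
                      lib_size = as.numeric(libs[-1]))
}

#' Write a region count matrix (regions BED + counts TSV)
#' @param m a [region_count_matrix()].
#' @param bed_path,counts_path output paths.
#' @export
write_region_counts <- function(m, bed_path, counts_path) {
  write_bed(m$regions, bed_path)
  con <- file(counts_path, "w")
  writeLines(paste(colnames(m$counts), collapse = "\t"), con)
  writeLines(paste(c("#condition", m$condition), collapse = "\t"), con)
  writeLines(paste(c("#lib_size", m$lib_size), collapse = "\t"), con)
  utils::write.table(m$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(counts_path)
}

#' Read a dense-segment BED back into a segmentation
#'
#' Inverse of [write_segmentation_bed()] for one condition.
#'
#' @param path segment BED with state labels `E<k>` in the name column.
#' @param condition condition label to file the states under.
#' @param bin_size bin width in bp.
#' @param genome named chromosome lengths (defines bin counts).
#' @return A `segmentation` object holding this condition only.
#' @export
read_segmentation_bed <- function(path, condition, bin_size, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          colClasses = c("character", "numeric", "numeric", "character"))
  labels <- list()
  K <- 0L
  for (chr in names(genome)) {
    nb <- as.integer(ceiling(genome[[chr]] / bin_size))
    v <- integer(nb)
    sel <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(sel) > 0L) {
      st <- as.integer(sub("^E", "", sel$name))
      b1 <- sel$start %/% bin_size + 1L
      b2 <- pmin((sel$end - 1L) %/% bin_size + 1L, nb)
      for (i in seq_len(nrow(sel))) v[b1[i]:b2[i]] <- st[i]
      K <- max(K, max(st))
    }
    labels[[chr]] <- v
  }
  states <- list(); states[[condition]] <- labels
  structure(list(states = states, K = K, bin_size = bin_size),
            class = "segmentation")
}
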