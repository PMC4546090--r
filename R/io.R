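# I/O for cytosine call tables, BED intervals, gene models and expression.
# All internal coordinates are 0-based half-open; conversion to/from the
# 1-based conventions of on-disk formats happens only in this file.

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct and validate a cytosine call table
#'
#' The atom of all methylation math: one row per cytosine (or per merged
#' CpG dyad after [merge_symmetric_cg()]) holding methylated and total
#' read counts, strand, and trinucleotide context class.
#'
#' @param df data.frame with columns `chrom`, `pos` (0-based), `strand`
#'   (`"+"`, `"-"`, or `"*"` for strand-merged records), `context`
#'   (`"CG"`, `"CHG"`, `"CHH"`), `n_meth`, `n_total`. An optional
#'   `dinucleotide` column (`"CA"`, `"CT"`, `"CC"`, `"CG"`) is preserved.
#' @param assay `"BS"` or `"oxBS"`.
#' @param compartment `"genome"`, `"spike_in"`, or
#'   `"repeat_consensus:<name>"` for satellite-consensus calls.
#' @param stage,replicate free-form sample labels.
#' @return the validated data.frame with the source tags attached as
#'   attributes `assay`, `compartment`, `stage`, `replicate`.
#' @export
cytosine_calls <- function(df, assay = "BS", compartment = "genome",
                           stage = NA_character_, replicate = NA_character_) {
  required <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("call table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!assay %in% c("BS", "oxBS")) stop("assay must be 'BS' or 'oxBS'")
  if (nrow(df)) {
    if (any(df$n_meth < 0) || any(df$n_total < 0)) {
      stop("negative read counts")
    }
    if (any(df$n_meth > df$n_total)) stop("n_meth exceeds n_total")
    bad_ctx <- setdiff(unique(df$context), VALID_CONTEXTS)
    if (length(bad_ctx)) stop("unknown context(s): ", paste(bad_ctx, collapse = ", "))
    if (anyDuplicated(df[, c("chrom", "pos", "strand")])) {
      stop("duplicate (chrom, pos, strand) records")
    }
  }
  df <- as.data.frame(df)
  attr(df, "assay") <- assay
  attr(df, "compartment") <- compartment
  attr(df, "stage") <- stage
  attr(df, "replicate") <- replicate
  df
}

#' Read a Bismark-style cytosine report
#'
#' Expects the tab-separated cytosine-report dialect: chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context class,
#' and (optionally) the trinucleotide. Positions are shifted to 0-based on
#' read; `n_total = methylated + unmethylated`. Malformed rows (negative
#' counts, unknown strand or context, non-numeric counts) are dropped with
#' a warning reporting their line numbers.
#'
#' @inheritParams cytosine_calls
#' @param path file path.
#' @return a [cytosine_calls()] table.
#' @export
read_cytosine_report <- function(path, assay = "BS", compartment = "genome",
                                 stage = NA_character_,
                                 replicate = NA_character_) {
  if (!file.exists(path)) stop("cannot read cytosine report: ", path)
  if (file.info(path)$size == 0) {
    warning("empty cytosine report: ", path)
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), context = character(),
                        n_meth = integer(), n_total = integer())
    return(cytosine_calls(empty, assay, compartment, stage, replicate))
  }
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", fill = TRUE)
  if (ncol(raw) < 6L) stop("cytosine report needs >= 6 tab-separated columns")
  pos1 <- suppressWarnings(as.integer(raw[[2]]))
  nm <- suppressWarnings(as.integer(raw[[4]]))
  nu <- suppressWarnings(as.integer(raw[[5]]))
  ok <- !is.na(pos1) & pos1 >= 1L &
    !is.na(nm) & nm >= 0L & !is.na(nu) & nu >= 0L &
    raw[[3]] %in% c("+", "-") & raw[[6]] %in% VALID_CONTEXTS
  if (any(!ok)) {
    warning(sum(!ok), " malformed row(s) rejected at line(s): ",
            paste(utils::head(which(!ok), 20L), collapse = ", "))
  }
  df <- data.frame(
    chrom = raw[[1]][ok],
    pos = pos1[ok] - 1L,
    strand = raw[[3]][ok],
    context = raw[[6]][ok],
    n_meth = nm[ok],
    n_total = nm[ok] + nu[ok]
  )
  if (ncol(raw) >= 7L) {
    tri <- raw[[7]][ok]
    df$dinucleotide <- ifelse(nchar(tri) >= 2L, substr(tri, 1L, 2L), NA_character_)
  }
  cytosine_calls(df, assay, compartment, stage, replicate)
}

#' Write a cytosine call table as a Bismark-style report
#'
#' Inverse of [read_cytosine_report()]: 0-based positions are written back
#' as 1-based and `n_total` is split into methylated/unmethylated counts.
#' Only stranded (unmerged) tables can be represented in this dialect, so
#' strand-merged records (strand `"*"`) are rejected.
#'
#' @param calls a stranded cytosine call table.
#' @param path output path.
#' @export
write_cytosine_report <- function(calls, path) {
  if (nrow(calls) && any(calls$strand == "*")) {
    stop("write_cytosine_report expects a stranded (unmerged) table")
  }
  out <- data.table::data.table(
    chrom = calls$chrom,
    pos = calls$pos + 1L,
    strand = calls$strand,
    n_meth = calls$n_meth,
    n_unmeth = calls$n_total - calls$n_meth,
    context = calls$context
  )
  if (!is.null(calls$dinucleotide)) out[, "tri" := calls$dinucleotide]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Intervals are already 0-based half-open internally, so coordinates are
#' written verbatim. Optional `name` and `score` columns become BED
#' columns 4-5.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) && any(intervals$end <= intervals$start)) {
    stop("BED intervals must satisfy end > start")
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open, no header).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("cannot read BED: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  raw <- data.table::fread(path, header = FALSE, sep = "\t")
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 4L) names(raw)[4] <- "name"
  if (ncol(raw) >= 5L) names(raw)[5] <- "score"
  as.data.frame(raw)
}

#' Read a gene table
#'
#' TSV with header columns `id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open). The transcription start/end sites are derived by
#' strand: TSS = `start` on `+`, `end` on `-`.
#'
#' @param path gene table path.
#' @return data.frame of gene models with derived `tss` and `tes`.
#' @export
read_gene_table <- function(path) {
  genes <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  required <- c("id", "chrom", "start", "end", "strand")
  if (!all(required %in% names(genes))) {
    stop("gene table needs columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(genes$id)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strands must be '+' or '-'")
  gene_models(genes)
}

#' Derive TSS/TES for a gene data.frame
#'
#' @param genes data.frame with `id`, `chrom`, `start`, `end`, `strand`.
#' @return the same data.frame with `tss` and `tes` columns added.
#' @export
gene_models <- function(genes) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes
}

#' Read a per-stage FPKM expression table
#'
#' TSV with header: a gene `id` column followed by one non-negative FPKM
#' column per stage. Non-numeric or negative cells and duplicate gene ids
#' are fatal.
#'
#' @param path expression TSV path.
#' @param stages optional character vector of stage columns that must all
#'   be present.
#' @return data.frame keyed by `id` with numeric stage columns.
#' @export
read_expression_table <- function(path, stages = NULL) {
  expr <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                          colClasses = list(character = 1)))
  if (names(expr)[1] != "id") names(expr)[1] <- "id"
  if (anyDuplicated(expr$id)) stop("duplicate gene id(s) in expression table")
  if (!is.null(stages)) {
    absent <- setdiff(stages, names(expr))
    if (length(absent)) stop("missing stage column(s): ",
                             paste(absent, collapse = ", "))
  }
  for (col in setdiff(names(expr), "id")) {
    v <- suppressWarnings(as.numeric(expr[[col]]))
    if (anyNA(v)) {
      stop("non-numeric FPKM in column '", col, "' for gene(s): ",
           paste(utils::head(expr$id[is.na(v)], 5L), collapse = ", "))
    }
    if (any(v < 0)) stop("negative FPKM in column '", col, "'")
    expr[[col]] <- v
  }
  expr
}
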