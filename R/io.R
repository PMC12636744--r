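## On-disk formats. MetaPhlAn-style merged TSV for taxa, plain TSV for gene
## families / cytokines / metadata / results, JSON for truth and config.
## Tables are stored in percent (MetaPhlAn convention); downstream math
## converts to proportions internally exactly once.

rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__", sgb = "t__")

#' Read a MetaPhlAn-style merged abundance TSV
#'
#' Expects a first column of pipe-delimited lineages with rank prefixes
#' `k__` through `t__` and one numeric column per sample (percent scale).
#' Comment lines starting with `#` are skipped. Only rows whose terminal rank
#' matches `level` are retained, so each input row belongs to exactly one
#' rank's table.
#'
#' @param path TSV file path.
#' @param level taxonomic rank to retain; `"sgb"` (terminal `t__` rows,
#'   default) or any of kingdom...species.
#' @param renormalize if `TRUE`, rescale each sample to sum to 100; by
#'   default samples that do not sum to 100 (unclassified mass) are accepted
#'   with a warning.
#' @return An [abundance_table()] (samples x taxa, taxon ids are the terminal
#'   rank labels, full lineages kept as taxonomy).
#' @export
read_metaphlan_merged <- function(path, level = "sgb", renormalize = FALSE) {
  level <- match.arg(level, names(rank_prefixes))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no rows at requested rank", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop(sprintf("duplicate sample columns: %s",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")),
         call. = FALSE)
  }
  body <- lines[-1]
  lineno <- lineno[-1]
  pref <- rank_prefixes[[level]]
  rows <- list(); lineages <- character(0)
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    lineage <- f[1]
    terms <- strsplit(lineage, "|", fixed = TRUE)[[1]]
    last <- terms[length(terms)]
    lastpref <- substr(last, 1, 3)
    if (!lastpref %in% rank_prefixes) {
      stop(sprintf("line %d: unknown rank prefix '%s'", lineno[i], lastpref),
           call. = FALSE)
    }
    if (lastpref != pref) next
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals)) {
      stop(sprintf("line %d: non-numeric abundance cell", lineno[i]),
           call. = FALSE)
    }
    if (length(vals) != length(samples)) {
      stop(sprintf("line %d: expected %d values, got %d", lineno[i],
                   length(samples), length(vals)), call. = FALSE)
    }
    rows[[sub(pref, "", last, fixed = TRUE)]] <- vals
    lineages <- c(lineages, setNames(lineage, sub(pref, "", last, fixed = TRUE)))
  }
  if (!length(rows)) stop("no rows at requested rank", call. = FALSE)
  m <- t(do.call(rbind, rows))
  rownames(m) <- samples
  rs <- rowSums(m)
  off <- abs(rs - 100) > 0.5
  if (any(off)) {
    if (renormalize) {
      m <- 100 * m / rs
    } else {
      warning(sprintf(
        "%d sample(s) do not sum to 100 (unclassified mass); range %.2f-%.2f",
        sum(off), min(rs), max(rs)), call. = FALSE)
    }
  }
  abundance_table(m, taxonomy = lineages)
}

#' Write an abundance table as a MetaPhlAn-style merged TSV
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @export
write_metaphlan_merged <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  lineage <- if (!is.null(table$taxonomy)) {
    unname(table$taxonomy[table$taxon_ids])
  } else paste0("t__", table$taxon_ids)
  df <- data.frame(clade_name = lineage, t(table$values),
                   check.names = FALSE)
  writeLines(c("#vaxbiome merged abundance table",
               paste(c("clade_name", table$sample_ids), collapse = "\t")),
             path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a sample metadata TSV
#' @param path TSV with columns sample_id, subject_id, cohort, ...
#' @return A [covariate_table()].
#' @export
read_metadata <- function(path) {
  covariate_table(read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#"))
}

#' Read a cytokine panel TSV
#' @param path TSV in the long format written by [write_cytokines()].
#' @param assay assay kind, see [cytokine_panel()].
#' @return A [cytokine_panel()].
#' @export
read_cytokines <- function(path, assay = "multiplex-PBMC") {
  cytokine_panel(read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#"),
                 assay = assay)
}

#' Write a cytokine panel / metadata / gene-family table as TSV
#' @param x the object to write.
#' @param path output path.
#' @name writers
#' @export
write_cytokines <- function(x, path) {
  stopifnot(inherits(x, "cytokine_panel"))
  write_tsv_with_header(x$data, path)
}

#' @rdname writers
#' @export
write_metadata <- function(x, path) {
  stopifnot(inherits(x, "covariate_table"))
  write_tsv_with_header(x$data, path)
}

#' @rdname writers
#' @export
write_gene_families <- function(x, path) {
  stopifnot(inherits(x, "gene_family_table"))
  df <- data.frame(ec_id = x$ec_ids, t(x$values), check.names = FALSE)
  write_tsv_with_header(df, path)
}

#' Read a gene-family RPK TSV (EC rows, sample columns)
#' @param path TSV path.
#' @return A [gene_family_table()].
#' @export
read_gene_families <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  gene_family_table(t(as.matrix(df[, -1, drop = FALSE])),
                    sample_ids = colnames(df)[-1], ec_ids = df[[1]])
}

write_tsv_with_header <- function(df, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    writeLines(sprintf("# vaxbiome %s",
                       as.character(utils::packageVersion("vaxbiome"))), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results data.frame as TSV with a provenance header
#'
#' @param table data.frame of results.
#' @param path output path.
#' @param config optional [analysis_config()]; a hash of it is recorded in
#'   the header comment.
#' @export
write_results <- function(table, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (!is.null(config)) {
    sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))) %% 1e8
  } else NA
  writeLines(sprintf("# vaxbiome %s config_hash=%s",
                     as.character(utils::packageVersion("vaxbiome")),
                     format(hash)), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
             comment.char = "#")
}

#' Join an abundance table with metadata, failing fast on mismatches
#'
#' @param table an [abundance_table()] or [gene_family_table()].
#' @param metadata a [covariate_table()].
#' @param require columns that must be present (e.g. `c("age","sex")` when a
#'   model requests adjustment); missing ones raise an error here, at model
#'   construction, not at parse time.
#' @return The metadata data.frame reordered to the table's samples.
#' @export
align_metadata <- function(table, metadata, require = character(0)) {
  stopifnot(inherits(metadata, "covariate_table"))
  md <- metadata$data
  miss <- setdiff(require, names(md))
  if (length(miss)) {
    stop(sprintf("metadata missing required columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ids <- table$sample_ids
  absent <- setdiff(ids, md$sample_id)
  if (length(absent)) {
    stop(sprintf("samples absent from metadata: %s",
                 paste(head(absent, 5), collapse = ", ")), call. = FALSE)
  }
  md[match(ids, md$sample_id), , drop = FALSE]
}

#' Write a simulated cohort set to a directory
#'
#' Emits, per cohort, a MetaPhlAn-style merged TSV, a gene-family TSV, a
#' cytokine TSV and a metadata TSV, plus a `truth.json`.
#'
#' @param set a `synthetic_cohort_set` from [simulate_cohort_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_set <- function(set, dir) {
  stopifnot(inherits(set, "synthetic_cohort_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in names(set$abundance)) {
    write_metaphlan_merged(set$abundance[[co]],
                           file.path(dir, sprintf("%s_abundance.tsv", co)))
    write_gene_families(set$gene_families[[co]],
                        file.path(dir, sprintf("%s_genefamilies.tsv", co)))
    write_cytokines(set$cytokines[[co]],
                    file.path(dir, sprintf("%s_cytokines.tsv", co)))
    write_metadata(set$metadata[[co]],
                   file.path(dir, sprintf("%s_metadata.tsv", co)))
  }
  truth <- list(
    signal_taxa = as.list(set$truth$signal_taxa),
    signal_genes = as.list(set$truth$signal_genes[set$truth$signal_genes != 0]),
    cluster_labels = lapply(set$truth$cluster_labels, as.list)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
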