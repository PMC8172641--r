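#' Validate a gene-order table
#'
#' A genome is carried as a tibble with one row per gene and columns `chrom`,
#' `rank` (0-based, gapless within each chromosome), `gene_id` (unique
#' genome-wide), `family_id` and optional `strand` (`+`, `-` or `unknown`).
#' Physical coordinates are deliberately not modelled: collinearity and depth
#' are measured in genes.
#'
#' @param genome A data frame with the columns above.
#' @return The validated genome as a tibble sorted by `(chrom, rank)`.
#' @export
validate_gene_order <- function(genome) {
  genome <- as_tibble(genome)
  need <- c("chrom", "rank", "gene_id", "family_id")
  missing_cols <- setdiff(need, names(genome))
  if (length(missing_cols) > 0) {
    abort(paste0("gene-order table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"strand" %in% names(genome)) genome$strand <- "unknown"
  if (!all(genome$strand %in% c("+", "-", "unknown"))) {
    abort("strand must be one of '+', '-', 'unknown'")
  }
  if (anyDuplicated(genome$gene_id)) {
    dup <- unique(genome$gene_id[duplicated(genome$gene_id)])
    abort(paste0("duplicate gene_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  genome <- arrange(genome, .data$chrom, .data$rank)
  bad <- genome %>%
    group_by(.data$chrom) %>%
    summarise(ok = identical(as.integer(.data$rank),
                             seq_len(n()) - 1L), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(paste0("rank gap: ranks must be 0-based and gapless on chromosome(s) ",
                 paste(bad$chrom, collapse = ", ")))
  }
  genome$rank <- as.integer(genome$rank)
  genome[c("chrom", "rank", "gene_id", "family_id", "strand")]
}

#' Read a gene-order table from TSV
#'
#' @param path Path to a tab-separated file with header columns
#'   `chrom, rank, gene_id, family_id[, strand]`.
#' @return A validated gene-order tibble (see [validate_gene_order()]).
#' @export
read_gene_order <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_gene_order(tab)
}

#' Write a gene-order table to TSV
#'
#' @param genome A gene-order tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_order <- function(genome, path) {
  readr::write_tsv(validate_gene_order(genome), path, progress = FALSE)
  invisible(path)
}

#' Validate a table of pairwise synonymous divergences
#'
#' Rows carry unordered gene pairs with their Ks value and optional
#' `family_id` / `node_id` tags. Symmetric duplicates (`a,b` and `b,a` with
#' equal Ks) are collapsed; the same pair with conflicting Ks is an error, as
#' are negative or non-finite values.
#'
#' @param ks_table Data frame with columns `gene_a`, `gene_b`, `ks`.
#' @return A validated tibble with one row per unordered pair.
#' @export
validate_ks_table <- function(ks_table) {
  tab <- as_tibble(ks_table)
  need <- c("gene_a", "gene_b", "ks")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("Ks table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab$ks <- as.numeric(tab$ks)
  if (any(!is.finite(tab$ks))) abort("Ks values must be finite numbers")
  if (any(tab$ks < 0)) abort("Ks values must be >= 0")
  if (!"family_id" %in% names(tab)) tab$family_id <- NA_character_
  if (!"node_id" %in% names(tab)) tab$node_id <- NA_character_
  swap <- tab$gene_a > tab$gene_b
  tmp <- tab$gene_a[swap]
  tab$gene_a[swap] <- tab$gene_b[swap]
  tab$gene_b[swap] <- tmp
  tab <- distinct(tab, .data$gene_a, .data$gene_b, .data$ks,
                  .data$family_id, .data$node_id)
  key <- paste(tab$gene_a, tab$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- unique(key[duplicated(key)])[1]
    abort(paste0("conflicting Ks values for pair ",
                 gsub("\r", " / ", bad, fixed = TRUE)))
  }
  tab[c("gene_a", "gene_b", "ks", "family_id", "node_id")]
}

#' Read a Ks table from TSV
#'
#' @param path Path to a tab-separated file with header columns
#'   `gene_a, gene_b, ks[, family_id, node_id]`.
#' @return A validated Ks tibble (see [validate_ks_table()]).
#' @export
read_ks_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_ks_table(tab)
}

#' Write a Ks table to TSV
#'
#' @param ks_table A Ks tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ks_table <- function(ks_table, path) {
  readr::write_tsv(validate_ks_table(ks_table), path, progress = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Bundles the tunable thresholds of the pipeline with their defaults: the Ks
#' fitting window `[0.01, 3]`, mixture selection settings (up to 4 components,
#' 200 parametric-bootstrap replicates per test at level 0.05), anchor
#' chaining settings (gap of at most 10 intervening genes, at least 5 anchor
#' pairs per block), and MAPS settings (3000 simulated null trees, resampling
#' 1000 trees 100 times, minimum simulated WGD retention 0.2).
#'
#' @param seed Integer seed recorded with the run.
#' @param ... Named overrides for any default.
#' @return A named list of class `wgd_config`.
#' @export
wgd_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ks_window = c(0.01, 3),
    k_max = 4L, n_boot = 200L, alpha = 0.05,
    max_gap = 10L, min_pairs = 5L,
    n_null = 3000L, resample_size = 1000L, resample_reps = 100L,
    retention_min = 0.2
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  num <- c("ks_window", "k_max", "n_boot", "alpha", "max_gap", "min_pairs",
           "n_null", "resample_size", "resample_reps", "retention_min")
  if (any(unlist(cfg[num]) <= 0)) abort("all config thresholds must be positive")
  structure(cfg, class = "wgd_config")
}

#' Read a run configuration from a flat key=value file
#'
#' @param path Path to a text file of `key = value` lines (`#` comments
#'   allowed). `ks_window` may be given as two comma-separated numbers.
#' @return A `wgd_config` list.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- lapply(kv, function(x) {
    v <- as.numeric(strsplit(trimws(x[2]), ",")[[1]])
    if (any(is.na(v))) abort(paste0("non-numeric config value for ", x[1]))
    v
  })
  args <- setNames(vals, keys)
  if (!"seed" %in% keys) args <- c(list(seed = 1L), args)
  do.call(wgd_config, args)
}
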