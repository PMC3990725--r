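# Tabular I/O: TSV (tab-separated, UTF-8, header row) for data tables,
# JSON for the final report.

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a duplication panel table
#'
#' Reads a TSV with columns `stock_id`, `dp_name`, `interval` and
#' validates every interval; rejects duplicate stock ids and malformed or
#' reversed intervals with the offending row number.
#'
#' @param path Path to the panel TSV.
#' @return The panel data.frame.
#' @export
read_panel <- function(path) {
  panel <- read_tsv_strict(path)
  need <- c("stock_id", "dp_name", "interval")
  if (!all(need %in% names(panel)))
    stop("panel file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(panel)) {
    warning("empty panel file: ", path, call. = FALSE)
    return(panel)
  }
  dup <- panel$stock_id[duplicated(panel$stock_id)]
  if (length(dup))
    stop("duplicate stock ids in panel: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(panel))) {
    parsed <- tryCatch(parse_interval(panel$interval[i]), error = identity)
    if (inherits(parsed, "error"))
      stop("row ", i, " (", panel$stock_id[i], "): ",
           conditionMessage(parsed), call. = FALSE)
  }
  panel
}

#' Read a viability (stage-census) table
#'
#' Reads the per-replicate census TSV consumed by [screen_calls()]:
#' columns `stock_id`, `background`, `paternal_species`, `line`,
#' `replicate`, `n_fertilized`, `n_hatched`, `n_pupae`, `n_adults`,
#' `inseminated`; extra columns are carried through. Census monotonicity
#' (`n_fertilized >= n_hatched` and male `n_hatched >= n_pupae >=
#' n_adults >= 0`) is checked.
#'
#' @param path Path to the viability TSV.
#' @return The viability data.frame.
#' @export
read_viability <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("stock_id", "background", "paternal_species", "line",
            "replicate", "n_fertilized", "n_hatched", "n_pupae",
            "n_adults", "inseminated")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("viability file missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab$inseminated <- as.logical(tab$inseminated)
  bad <- tab$n_fertilized < tab$n_hatched | tab$n_hatched < tab$n_pupae |
    tab$n_pupae < tab$n_adults | tab$n_adults < 0
  if (any(bad))
    stop("census counts increase along development at rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  tab
}

#' Write a panel, viability, calls or regions table as TSV
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table_tsv <- function(x, path) write_tsv(x, path)

#' Write the pipeline report as JSON
#'
#' @param report Report list from [run_pipeline()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
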