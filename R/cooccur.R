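#' Homolog hit filter
#'
#' E-value cutoffs per component and the alignment-length tolerance used
#' to filter BLAST hits. Defaults carry the antiporter cutoffs used for
#' the acid-resistance systems (GadC 1e-100; AdiC and CadB 1e-120) plus
#' cutoffs for their regulators, and a 10% length tolerance: a hit is kept
#' when its length is within +/-10% of the query length.
#'
#' @param evalue_max named numeric vector, component -> e-value cutoff
#'   (hits must be strictly below it).
#' @param length_tolerance fraction in \[0,1); default 0.10.
#' @return an object of class `"homolog_filter"`.
#' @export
homolog_filter <- function(evalue_max = c(GadC = 1e-100, AdiC = 1e-120,
                                          CadB = 1e-120, GadE = 1e-20,
                                          CsiR = 1e-50, YdeO = 1e-60,
                                          GadB = 1e-80, GadW = 1e-100,
                                          GadX = 1e-100, EvgS = 1e-170,
                                          AdiA = 1e-170, AdiY = 1e-100,
                                          CadA = 1e-170, CadC = 1e-120,
                                          LysP = 1e-120, GadY = 1e-20),
                           length_tolerance = 0.10) {
  if (is.null(names(evalue_max)) || any(evalue_max <= 0))
    stop("`evalue_max` must be a named vector of positive cutoffs")
  if (length_tolerance < 0 || length_tolerance >= 1)
    stop("`length_tolerance` must be in [0, 1)")
  structure(list(evalue_max = evalue_max, length_tolerance = length_tolerance),
            class = "homolog_filter")
}

#' Filter raw homolog hits by e-value and length tolerance
#'
#' Keeps rows with `evalue < cutoff(component)` and
#' `|hit_length - query_length| <= tolerance * query_length`, then retains
#' one best hit (lowest e-value; ties broken by accession order) per
#' (component, species).
#'
#' @param hits data frame with columns `component`, `species_id`,
#'   `accession`, `evalue`, `hit_length`, `query_length`; extra columns
#'   (e.g. taxonomy) are preserved.
#' @param filter a [homolog_filter()].
#' @return the filtered table (subset of the input rows).
#' @export
filter_hits <- function(hits, filter = homolog_filter()) {
  stopifnot(inherits(filter, "homolog_filter"), is.data.frame(hits))
  need <- c("component", "species_id", "accession", "evalue",
            "hit_length", "query_length")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(hits)) return(hits)
  unknown <- setdiff(unique(hits$component), names(filter$evalue_max))
  if (length(unknown))
    stop("no e-value cutoff configured for component(s): ",
         paste(unknown, collapse = ", "))
  cut <- filter$evalue_max[hits$component]
  keep <- hits$evalue < cut &
    abs(hits$hit_length - hits$query_length) <=
      filter$length_tolerance * hits$query_length
  out <- hits[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  ## one best hit per (component, species): lowest e-value, then accession
  out <- out[order(out$component, out$species_id, out$evalue, out$accession), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("component", "species_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a presence/absence matrix anchored on one component
#'
#' One row per species that carries the anchor component; one 0/1 column
#' per component, flagging whether the species appears in that component's
#' filtered homolog table.
#'
#' @param table filtered homolog table (as from [filter_hits()]) covering
#'   all components, or a list of per-component tables.
#' @param anchor anchor component name; must be present in the table.
#' @return a data frame of class `c("presence_matrix", "data.frame")`:
#'   `species_id` plus one 0/1 column per component, attribute `anchor`.
#' @export
build_presence_matrix <- function(table, anchor) {
  if (is.list(table) && !is.data.frame(table))
    table <- do.call(rbind, table)
  stopifnot(is.data.frame(table))
  comps <- unique(table$component)
  if (!anchor %in% comps) stop("unknown anchor `", anchor, "`")
  sp_of <- function(comp) unique(table$species_id[table$component == comp])
  anchor_sp <- sort(sp_of(anchor))
  if (!length(anchor_sp)) stop("anchor table is empty")
  out <- data.frame(species_id = anchor_sp, stringsAsFactors = FALSE)
  for (comp in c(anchor, setdiff(comps, anchor)))
    out[[comp]] <- as.integer(anchor_sp %in% sp_of(comp))
  attr(out, "anchor") <- anchor
  class(out) <- c("presence_matrix", "data.frame")
  out
}

#' Co-occurrence percentages of a presence matrix
#'
#' For each component column, the percentage of anchor-carrying species
#' that also carry it. The anchor column is 100% by construction.
#'
#' @param matrix a presence matrix ([build_presence_matrix()] or
#'   [simulate_presence_table()] output, or any data frame of 0/1 flags
#'   with a `species_id` column).
#' @return named numeric vector of percentages in \[0, 100\].
#' @export
cooccurrence_summary <- function(matrix) {
  stopifnot(is.data.frame(matrix), nrow(matrix) > 0)
  cols <- setdiff(names(matrix), "species_id")
  vapply(matrix[cols], function(v) 100 * mean(v == 1), numeric(1))
}

#' Conditional co-occurrence percentage
#'
#' Percentage of rows with `given == 1` that also have `target == 1`.
#'
#' @param matrix presence matrix.
#' @param given,target column names.
#' @return scalar percentage.
#' @export
cooccurrence_conditional <- function(matrix, given, target) {
  stopifnot(all(c(given, target) %in% names(matrix)))
  g <- matrix[[given]] == 1
  if (!any(g)) return(NA_real_)
  100 * mean(matrix[[target]][g] == 1)
}

#' Taxonomic composition of a homolog table
#'
#' Fraction of species per taxon at the chosen rank, sorted descending;
#' species without a label are grouped as `"unassigned"`.
#'
#' @param table homolog table with a taxonomy column named after `rank`.
#' @param rank `"family"`, `"genus"` or `"phylum"`.
#' @return named numeric vector of fractions summing to 1 (empty for an
#'   empty table).
#' @export
taxonomy_summary <- function(table, rank = c("family", "genus", "phylum")) {
  rank <- match.arg(rank)
  if (!rank %in% names(table))
    stop("taxonomy column `", rank, "` not present")
  if (!nrow(table)) return(stats::setNames(numeric(0), character(0)))
  sp <- table[!duplicated(table$species_id), , drop = FALSE]
  lab <- as.character(sp[[rank]])
  lab[is.na(lab) | !nzchar(lab)] <- "unassigned"
  tab <- sort(table(lab), decreasing = TRUE)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Read / write a presence matrix as TSV
#'
#' Plain TSV with a `species_id` column and one 0/1 column per component;
#' the first flag column is taken as the anchor unless given.
#'
#' @param path file path.
#' @param matrix presence matrix (for writing).
#' @param anchor anchor column name; default: first flag column.
#' @return the presence matrix (read) or `path` invisibly (write).
#' @export
read_presence_tsv <- function(path, anchor = NULL) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species_id" %in% names(m)) stop("missing `species_id` column")
  if (is.null(anchor)) anchor <- setdiff(names(m), "species_id")[1]
  attr(m, "anchor") <- anchor
  class(m) <- c("presence_matrix", "data.frame")
  m
}

#' @rdname read_presence_tsv
#' @export
write_presence_tsv <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a presence column as an iTOL binary-annotation ring
#'
#' Writes an iTOL `DATASET_BINARY` text file flagging, per species, the
#' presence of one component, for ring display around a tree.
#'
#' @param matrix presence matrix.
#' @param component column to export.
#' @param path output file path.
#' @param color ring colour (hex).
#' @return `path`, invisibly.
#' @export
write_itol_binary <- function(matrix, component, path, color = "#1f78b4") {
  stopifnot(component %in% names(matrix))
  hdr <- c("DATASET_BINARY", "SEPARATOR TAB",
           paste0("DATASET_LABEL\t", component),
           paste0("COLOR\t", color),
           paste0("FIELD_SHAPES\t1"),
           paste0("FIELD_LABELS\t", component),
           paste0("FIELD_COLORS\t", color),
           "DATA")
  rows <- paste(matrix$species_id,
                ifelse(matrix[[component]] == 1, "1", "-1"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
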