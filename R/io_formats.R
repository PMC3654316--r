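# Text I/O: unmerged reflection files (XDS-ASCII-style dialect and TSV),
# the XML results summary, and plot-data tables.

#' Construct a dataset header
#'
#' Acquisition metadata carried at the top of a reflection file.
#'
#' @param cell a [unit_cell()]
#' @param group_symbol symmetry-group symbol (registry entry)
#' @param oscillation_range degrees per image, > 0
#' @param starting_angle degrees
#' @param template_name image template name (free text)
#' @param n_images number of images, >= 1
#' @param dataset_id dataset label
#' @return list of class `dataset_header`
#' @export
dataset_header <- function(cell, group_symbol, oscillation_range = 1,
                           starting_angle = 0, template_name = "data_####.cbf",
                           n_images = 100L, dataset_id = "ds1") {
  if (!is.finite(oscillation_range) || oscillation_range <= 0)
    stop("oscillation_range must be > 0")
  if (n_images < 1) stop("n_images must be >= 1")
  structure(list(cell = cell, group_symbol = group_symbol,
                 oscillation_range = oscillation_range,
                 starting_angle = starting_angle,
                 template_name = template_name,
                 n_images = as.integer(n_images),
                 dataset_id = as.character(dataset_id)),
            class = "dataset_header")
}

.num17 <- function(x) sprintf("%.17g", x)

#' Write an unmerged reflection file
#'
#' Two dialects: `"xds_ascii"` ('!'-prefixed KEY=VALUE header lines,
#' whitespace-separated `h k l intensity sigma image` records, an
#' `!END_OF_DATA` terminator) and `"tsv"` ('#key=value' comment header, then
#' a tab-separated table).  Numbers are written with 17 significant digits
#' so [read_reflections()] inverts the write bit-identically.
#'
#' @param header a [dataset_header()]
#' @param table reflection table
#' @param path output file
#' @param dialect `"xds_ascii"` or `"tsv"`
#' @return `path`, invisibly
#' @export
write_reflections <- function(header, table, path, dialect = c("xds_ascii", "tsv")) {
  dialect <- match.arg(dialect)
  table <- as_reflection_table(table)
  cl <- header$cell
  kv <- c(UNIT_CELL_CONSTANTS = paste(.num17(c(cl$a, cl$b, cl$c, cl$alpha,
                                               cl$beta, cl$gamma)),
                                      collapse = " "),
          SPACE_GROUP_SYMBOL = header$group_symbol,
          OSCILLATION_RANGE = .num17(header$oscillation_range),
          STARTING_ANGLE = .num17(header$starting_angle),
          NAME_TEMPLATE_OF_DATA_FRAMES = header$template_name,
          N_IMAGES = as.character(header$n_images),
          DATASET_ID = header$dataset_id)
  if (dialect == "xds_ascii") {
    lines <- c(sprintf("!%s=%s", names(kv), kv),
               "!ITEM_LIST=H K L IOBS SIGMA IMAGE",
               sprintf("%d %d %d %s %s %d", table$h, table$k, table$l,
                       .num17(table$intensity), .num17(table$sigma),
                       table$image),
               "!END_OF_DATA")
  } else {
    lines <- c(sprintf("#%s=%s", names(kv), kv),
               paste(c("h", "k", "l", "intensity", "sigma", "image"),
                     collapse = "\t"),
               sprintf("%d\t%d\t%d\t%s\t%s\t%d", table$h, table$k, table$l,
                       .num17(table$intensity), .num17(table$sigma),
                       table$image))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an unmerged reflection file
#'
#' Inverse of [write_reflections()].  Rows with sigma <= 0 are dropped and
#' counted (`n_dropped`), mirroring how unusable measurements are discarded
#' on ingest.
#'
#' @param path input file
#' @param dialect `"xds_ascii"` or `"tsv"`
#' @return list with `header` ([dataset_header()]), `table` (reflection
#'   table) and `n_dropped`
#' @export
read_reflections <- function(path, dialect = c("xds_ascii", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  prefix <- if (dialect == "xds_ascii") "!" else "#"
  hdr_lines <- lines[startsWith(lines, prefix)]
  hdr_lines <- hdr_lines[grepl("=", hdr_lines, fixed = TRUE)]
  keys <- sub("=.*$", "", substring(hdr_lines, 2))
  vals <- sub("^[^=]*=", "", substring(hdr_lines, 2))
  kv <- stats::setNames(vals, keys)
  need <- c("UNIT_CELL_CONSTANTS", "SPACE_GROUP_SYMBOL", "OSCILLATION_RANGE",
            "STARTING_ANGLE", "N_IMAGES")
  miss <- setdiff(need, keys)
  if (length(miss))
    stop("format error: missing mandatory header field(s): ",
         paste(miss, collapse = ", "))
  cc <- as.numeric(strsplit(trimws(kv[["UNIT_CELL_CONSTANTS"]]), "\\s+")[[1]])
  if (length(cc) != 6 || any(!is.finite(cc)))
    stop("format error: UNIT_CELL_CONSTANTS needs 6 numbers")
  header <- dataset_header(
    cell = unit_cell(cc[1], cc[2], cc[3], cc[4], cc[5], cc[6]),
    group_symbol = trimws(kv[["SPACE_GROUP_SYMBOL"]]),
    oscillation_range = as.numeric(kv[["OSCILLATION_RANGE"]]),
    starting_angle = as.numeric(kv[["STARTING_ANGLE"]]),
    template_name = if ("NAME_TEMPLATE_OF_DATA_FRAMES" %in% keys)
      kv[["NAME_TEMPLATE_OF_DATA_FRAMES"]] else "",
    n_images = as.integer(kv[["N_IMAGES"]]),
    dataset_id = if ("DATASET_ID" %in% keys) kv[["DATASET_ID"]] else "ds1")

  is_data <- !startsWith(lines, prefix) & nzchar(trimws(lines))
  if (dialect == "tsv") {
    first <- which(is_data)[1]  # column header row
    if (!is.na(first)) is_data[first] <- FALSE
  }
  data_lines <- lines[is_data]
  if (!length(data_lines))
    return(list(header = header,
                table = reflection_table(integer(0), integer(0), integer(0),
                                         numeric(0), numeric(0), integer(0),
                                         character(0)),
                n_dropped = 0L))
  parts <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 6))
    stop("format error at line ", which(is_data)[which(nf != 6)[1]],
         ": expected 6 fields")
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 6,
              byrow = TRUE)
  if (any(!is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0)[1]
    stop("format error at line ", which(is_data)[bad], ": non-numeric field")
  }
  keep <- m[, 5] > 0
  tab <- reflection_table(h = m[keep, 1], k = m[keep, 2], l = m[keep, 3],
                          intensity = m[keep, 4], sigma = m[keep, 5],
                          image = m[keep, 6], dataset_id = header$dataset_id)
  list(header = header, table = tab, n_dropped = sum(!keep))
}

# ---- XML summary -----------------------------------------------------------

.xml_shell_node <- function(parent, row, name = "shell") {
  node <- xml2::xml_add_child(parent, name)
  for (f in c("d_max", "d_min", "n_obs", "n_unique", "n_theoretical",
              "completeness", "mean_i_over_sigma", "r_merge", "r_meas",
              "multiplicity")) {
    v <- row[[f]]
    xml2::xml_set_attr(node, f, if (is.null(v) || is.na(v)) "NA" else .num17(v))
  }
  node
}

#' Write the XML results summary
#'
#' One document containing, per Friedel branch, the per-shell statistics,
#' the overall row and the chosen resolution limit; plus rejection counts
#' and, when present, grouped-merge and SAD-triage blocks.  The layout is
#' this package's own schema (shipped as `extdata/summary_schema.xsd`); the
#' production system's database schema is not public.
#'
#' @param results a results bundle as produced by [run_fast()] (at minimum:
#'   `branches`, a named list with `shells`, `overall`, `cutoff`;
#'   optionally `n_rejected`, `grouped`, `sad`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_xml_summary <- function(results, path) {
  if (is.null(results$branches) || !length(results$branches))
    stop("validation error: results bundle has no Friedel branch")
  doc <- xml2::xml_new_root("autoproc_summary")
  xml2::xml_set_attr(doc, "n_rejected",
                     as.character(results$n_rejected %||% 0L))
  for (bn in names(results$branches)) {
    b <- results$branches[[bn]]
    miss <- setdiff(c("shells", "overall", "cutoff"), names(b))
    if (length(miss))
      stop("validation error: branch '", bn, "' missing section(s): ",
           paste(miss, collapse = ", "))
    node <- xml2::xml_add_child(doc, "branch")
    xml2::xml_set_attr(node, "friedel_merged",
                       if (identical(b$friedel_merged, FALSE)) "false" else "true")
    lim <- xml2::xml_add_child(node, "resolution_limit")
    xml2::xml_set_attr(lim, "d_min", .num17(b$cutoff$d_min_new))
    xml2::xml_set_attr(lim, "rule", b$cutoff$rule)
    for (i in seq_len(nrow(b$shells)))
      .xml_shell_node(node, as.list(b$shells[i, ]))
    .xml_shell_node(node, as.list(b$overall[1, ]), name = "overall")
  }
  if (!is.null(results$grouped)) {
    g <- results$grouped
    gn <- xml2::xml_add_child(doc, "grouped_merge")
    xml2::xml_set_attr(gn, "reference_id", g$reference_id)
    xml2::xml_set_attr(gn, "group_symbol", g$group_symbol)
    for (i in seq_along(g$datasets$dataset_id)) {
      dn <- xml2::xml_add_child(gn, "dataset")
      xml2::xml_set_attr(dn, "id", g$datasets$dataset_id[i])
      xml2::xml_set_attr(dn, "verdict", g$datasets$verdict[i])
      xml2::xml_set_attr(dn, "operator",
                         paste(as.integer(t(g$datasets$operator[[i]])),
                               collapse = " "))
    }
    for (inc in g$increments) {
      iv <- xml2::xml_add_child(gn, "increment")
      xml2::xml_set_attr(iv, "k", as.character(inc$k))
      xml2::xml_set_attr(iv, "completeness", .num17(inc$overall$completeness))
      xml2::xml_set_attr(iv, "mean_i_over_sigma",
                         .num17(inc$overall$mean_i_over_sigma))
      xml2::xml_set_attr(iv, "multiplicity", .num17(inc$overall$multiplicity))
    }
  }
  if (!is.null(results$sad)) {
    s <- results$sad
    sn <- xml2::xml_add_child(doc, "sad_triage")
    xml2::xml_set_attr(sn, "trigger", if (isTRUE(s$summary$trigger)) "true" else "false")
    xml2::xml_set_attr(sn, "estimated_mw", .num17(s$plan$estimated_mw))
    for (i in seq_len(nrow(s$summary$shells))) {
      an <- xml2::xml_add_child(sn, "anom_shell")
      r <- s$summary$shells[i, ]
      xml2::xml_set_attr(an, "d_max", .num17(r$d_max))
      xml2::xml_set_attr(an, "d_min", .num17(r$d_min))
      xml2::xml_set_attr(an, "n_pairs", as.character(r$n_pairs))
      xml2::xml_set_attr(an, "danom_over_sigma",
                         if (is.na(r$danom_over_sigma)) "NA"
                         else .num17(r$danom_over_sigma))
    }
    for (i in seq_len(nrow(s$plan$trials))) {
      tn <- xml2::xml_add_child(sn, "trial")
      xml2::xml_set_attr(tn, "solvent_fraction",
                         .num17(s$plan$trials$solvent_fraction[i]))
      xml2::xml_set_attr(tn, "hand", s$plan$trials$hand[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an XML summary against the shipped schema
#' @param path XML file
#' @return TRUE if valid, otherwise an error
#' @export
validate_xml_summary <- function(path) {
  schema <- xml2::read_xml(system.file("extdata", "summary_schema.xsd",
                                       package = "reflexio", mustWork = TRUE))
  ok <- xml2::xml_validate(xml2::read_xml(path), schema)
  if (!ok) stop("XML summary fails schema validation: ",
                paste(attr(ok, "errors"), collapse = "; "))
  TRUE
}

#' Write incremental-merge plot data
#'
#' One TSV row per (increment, shell) with completeness, mean I/sigma and
#' multiplicity — the numbers behind incremental-improvement bar charts.
#'
#' @param grouped a [merge_grouped()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_increment_plot_data <- function(grouped, path) {
  if (!length(grouped$increments))
    stop("grouped result has no increments")
  rows <- lapply(grouped$increments, function(inc) {
    data.table::data.table(increment = inc$k,
                           shell = inc$shells$shell,
                           d_max = inc$shells$d_max,
                           d_min = inc$shells$d_min,
                           completeness = inc$shells$completeness,
                           mean_i_over_sigma = inc$shells$mean_i_over_sigma,
                           multiplicity = inc$shells$multiplicity)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}
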