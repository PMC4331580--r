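# Canonical interchange format: UTF-8 TSV with a header row and '.' as
# the decimal separator.

.analyte_units <- c(fe2 = "umol_per_g", total_fe = "umol_per_g",
                    acetate = "umol_per_g", ch4_total = "umol",
                    co2_total = "umol", atom13_ch4 = "percent",
                    atom13_co2 = "percent", ph = "ph")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", check.names = FALSE)
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop("schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Write biogeochemical time courses as long-format TSV
#'
#' One row per (microcosm, time point, analyte) with the unit label, so
#' heterogeneous per-gram and per-vial measurements share one file.
#'
#' @param series_list Named list of series data.frames (as produced by
#'   [simulate_microcosm()]), names = microcosm ids.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_measurements <- function(series_list, path) {
  long <- lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    do.call(rbind, lapply(names(.analyte_units), function(an) {
      data.frame(microcosm_id = id, time_days = s$time_days, analyte = an,
                 value = s[[an]], unit = .analyte_units[[an]],
                 stringsAsFactors = FALSE)
    }))
  })
  .write_tsv(do.call(rbind, long), path)
  invisible(path)
}

#' Read biogeochemical time courses from long-format TSV
#'
#' Validates the schema (columns `microcosm_id`, `time_days`, `analyte`,
#' `value`, `unit`), rejects unknown analytes or wrong unit labels naming
#' the offending line, and checks per-microcosm invariants (strictly
#' increasing time, `fe2 <= total_fe`, atom percentages in `[0, 100]`).
#'
#' @param path TSV produced by [write_measurements()] (or by hand to the
#'   same schema).
#' @return Named list of wide per-microcosm data.frames.
#' @export
read_measurements <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("microcosm_id", "time_days", "analyte", "value",
                         "unit"), path)
  bad <- !(df$analyte %in% names(.analyte_units))
  if (any(bad)) {
    stop("schema violation in ", path, " line ", which(bad)[1] + 1,
         ": unknown analyte '", df$analyte[which(bad)[1]], "'",
         call. = FALSE)
  }
  wrong <- df$unit != .analyte_units[df$analyte]
  if (any(wrong)) {
    stop("schema violation in ", path, " line ", which(wrong)[1] + 1,
         ": analyte '", df$analyte[which(wrong)[1]], "' must carry unit '",
         .analyte_units[[df$analyte[which(wrong)[1]]]], "'", call. = FALSE)
  }
  out <- lapply(split(df, df$microcosm_id), function(d) {
    wide <- stats::reshape(
      d[, c("time_days", "analyte", "value")],
      idvar = "time_days", timevar = "analyte", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide <- wide[order(wide$time_days),
                 c("time_days", names(.analyte_units))]
    rownames(wide) <- NULL
    if (any(diff(wide$time_days) <= 0)) {
      stop("invalid series for ", d$microcosm_id[1],
           ": time must be strictly increasing", call. = FALSE)
    }
    if (any(wide$fe2 > wide$total_fe + 1e-9)) {
      stop("invalid series for ", d$microcosm_id[1],
           ": Fe(II) exceeds total Fe", call. = FALSE)
    }
    if (any(wide$atom13_ch4 < 0 | wide$atom13_ch4 > 100 |
            wide$atom13_co2 < 0 | wide$atom13_co2 > 100)) {
      stop("invalid series for ", d$microcosm_id[1],
           ": atom percentages must lie in [0, 100]", call. = FALSE)
    }
    wide
  })
  out
}

#' Write gradient profiles as TSV
#'
#' @param profiles Named list of [gradient_profile()]s; names are
#'   `microcosm_id:domain` keys or arbitrary ids.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_fractions <- function(profiles, path) {
  long <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    data.frame(microcosm_id = id, domain = attr(p, "domain"),
               fraction_index = p$fraction,
               buoyant_density_g_per_ml = p$bd, copies = p$copies,
               stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, long), path)
  invisible(path)
}

#' Read gradient profiles from TSV
#'
#' Schema: `microcosm_id`, `domain`, `fraction_index`,
#' `buoyant_density_g_per_ml`, `copies`.  Negative copy numbers are
#' rejected naming the offending line.
#'
#' @param path TSV path.
#' @return Named list of [gradient_profile()]s keyed by microcosm id.
#' @export
read_fractions <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("microcosm_id", "domain", "fraction_index",
                         "buoyant_density_g_per_ml", "copies"), path)
  neg <- df$copies < 0
  if (any(neg)) {
    stop("schema violation in ", path, " line ", which(neg)[1] + 1,
         ": negative copies value", call. = FALSE)
  }
  lapply(split(df, df$microcosm_id), function(d) {
    d <- d[order(d$fraction_index), ]
    gradient_profile(d$fraction_index, d$buoyant_density_g_per_ml,
                     d$copies, domain = d$domain[1],
                     treatment = d$microcosm_id[1])
  })
}

#' Write a taxon count table and its sample metadata
#'
#' @param counts Samples x genera integer matrix with dimnames.
#' @param metadata data.frame with columns `sample`, `soil`, `amendment`,
#'   `isotope`, `fraction`.
#' @param path Counts TSV path (first column `sample`).
#' @param meta_path Metadata TSV path.
#' @return The counts path, invisibly.
#' @export
write_taxa <- function(counts, metadata, path, meta_path) {
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  .write_tsv(metadata, meta_path)
  invisible(path)
}

#' Read a taxon count table and its sample metadata
#'
#' Validates non-negative integer counts and that every sample maps to
#' exactly one (soil, amendment, isotope) metadata row.
#'
#' @param path Counts TSV (first column `sample`, remaining columns
#'   genera).
#' @param meta_path Metadata TSV.
#' @return A list with `counts` (integer matrix) and `metadata`.
#' @export
read_taxa <- function(path, meta_path) {
  df <- .read_tsv(path)
  .require_columns(df, "sample", path)
  counts <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(counts) <- df$sample
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(rowSums(counts < 0 | counts != round(counts)) > 0)[1]
    stop("schema violation in ", path, " line ", bad + 1,
         ": counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  metadata <- .read_tsv(meta_path)
  .require_columns(metadata, c("sample", "soil", "amendment", "isotope"),
                   meta_path)
  if (anyDuplicated(metadata$sample)) {
    stop("schema violation in ", meta_path, ": duplicated sample ids",
         call. = FALSE)
  }
  miss <- setdiff(rownames(counts), metadata$sample)
  if (length(miss) > 0) {
    stop("samples without metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  list(counts = counts,
       metadata = metadata[match(rownames(counts), metadata$sample), ])
}
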