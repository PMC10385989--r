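# Readers/writers for the CSV and JSON dialects used by the pipeline,
# plus the packaged reference tables.  All readers validate headers
# (missing/extra columns are named) and report malformed numeric cells
# with their row numbers.

read_checked_csv <- function(path, required, numeric_cols,
                             optional = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) {
    stop("empty file: ", path, call. = FALSE)
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), c(required, optional))
  if (length(extra) > 0L) {
    stop("unexpected column(s) in ", basename(path), ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nm in intersect(numeric_cols, names(raw))) {
    x <- raw[[nm]]
    bad <- which(nzchar(x) & !is.na(x) & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad) > 0L) {
      stop("malformed numeric value(s) in column '", nm, "' of ",
           basename(path), " at row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    raw[[nm]] <- suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  }
  raw
}

.system_cols <- list(
  required = c("system_id", "category", "c", "e", "s", "a", "b", "v"),
  optional = c("name", "se_c", "se_e", "se_s", "se_a", "se_b", "se_v",
               "n", "sd", "r2", "f", "ref"),
  numeric = c("c", "e", "s", "a", "b", "v", "se_c", "se_e", "se_s",
              "se_a", "se_b", "se_v", "n", "sd", "r2", "f"))

#' Read a system-coefficient table
#'
#' CSV with header
#' `system_id,category,c,e,s,a,b,v` and optional diagnostic columns
#' (`name,se_c,...,se_v,n,sd,r2,f,ref`).  `c` may be empty for
#' literature systems whose intercept was not published.
#'
#' @param path CSV file path.
#' @return Validated data frame of systems.
#' @export
read_systems <- function(path) {
  out <- read_checked_csv(path, .system_cols$required,
                          .system_cols$numeric, .system_cols$optional)
  validate_systems(out)
  out
}

#' Write a system-coefficient table
#' @param systems data frame of systems.
#' @param path output CSV path.
#' @export
write_systems <- function(systems, path) {
  validate_systems(systems)
  utils::write.csv(systems, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a solute dataset
#'
#' CSV with header `name,E,S,A,B,V,log_pe` and optional
#' `pKa,acid_base,pH` columns (multiprotic compounds as
#' `";"`-separated lists in `pKa`/`acid_base`).
#'
#' @param path CSV file path.
#' @return Data frame of solute records.
#' @export
read_dataset <- function(path) {
  out <- read_checked_csv(
    path,
    required = c("name", "E", "S", "A", "B", "V", "log_pe"),
    numeric_cols = c("E", "S", "A", "B", "V", "log_pe", "pH"),
    optional = c("pKa", "acid_base", "pH", "log_pe_true"))
  validate_descriptors(out)
  # pKa stays character only for multiprotic ";"-lists; otherwise numeric
  for (nm in intersect(c("pKa", "acid_base"), names(out))) {
    out[[nm]][!nzchar(out[[nm]])] <- NA
  }
  if ("pKa" %in% names(out) && !any(grepl(";", out$pKa, fixed = TRUE))) {
    bad <- which(!is.na(out$pKa) &
                   is.na(suppressWarnings(as.numeric(out$pKa))))
    if (length(bad) > 0L) {
      stop("malformed numeric value(s) in column 'pKa' of ",
           basename(path), " at row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    out$pKa <- as.numeric(out$pKa)
  }
  out
}

#' Write a solute dataset
#' @param records data frame of solute records.
#' @param path output CSV path.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read raw PAMPA well measurements
#'
#' CSV with header
#' `compound,experiment_type,c_d0,c_dt,c_at,t_s,ph_donor,ph_acceptor`
#' where `experiment_type` is `iso` or `gradient`.  Replicate rows per
#' compound and type are kept as read; use [average_replicates()]
#' before the permeability calculation.
#'
#' @param path CSV file path.
#' @return Data frame of well measurements.
#' @export
read_wells <- function(path) {
  out <- read_checked_csv(
    path,
    required = c("compound", "experiment_type", "c_d0", "c_dt", "c_at",
                 "t_s", "ph_donor", "ph_acceptor"),
    numeric_cols = c("c_d0", "c_dt", "c_at", "t_s", "ph_donor",
                     "ph_acceptor"))
  bad <- which(!out$experiment_type %in% c("iso", "gradient"))
  if (length(bad) > 0L) {
    stop("experiment_type must be 'iso' or 'gradient' (row(s) ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  out
}

#' Average replicate wells per compound and experiment type
#'
#' Arithmetic mean of the concentrations over the 3-5 replicate
#' injections typically run per compound; time and pH must agree within
#' a replicate group.
#'
#' @param wells data frame from [read_wells()].
#' @return One row per (compound, experiment_type).
#' @export
average_replicates <- function(wells) {
  key <- interaction(wells$compound, wells$experiment_type, drop = TRUE)
  parts <- lapply(split(wells, key), function(g) {
    for (nm in c("t_s", "ph_donor", "ph_acceptor")) {
      if (length(unique(g[[nm]])) != 1L) {
        stop("replicates of compound '", g$compound[1], "' (",
             g$experiment_type[1], ") disagree on ", nm, call. = FALSE)
      }
    }
    data.frame(compound = g$compound[1],
               experiment_type = g$experiment_type[1],
               c_d0 = mean(g$c_d0), c_dt = mean(g$c_dt),
               c_at = mean(g$c_at), t_s = g$t_s[1],
               ph_donor = g$ph_donor[1], ph_acceptor = g$ph_acceptor[1],
               n_replicates = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Convert an averaged well row to a concentration record
#' @param row one-row data frame in the wells dialect.
#' @return A [concentration_record()].
#' @export
as_concentration_record <- function(row) {
  concentration_record(C_D0 = row$c_d0, C_Dt = row$c_dt, C_At = row$c_at,
                       t = row$t_s, pH_donor = row$ph_donor,
                       pH_acceptor = row$ph_acceptor)
}

#' Export a D' matrix to CSV or JSON
#' @param m matrix from [dprime_matrix()].
#' @param path output path; `.json` extension selects JSON.
#' @export
write_dprime_matrix <- function(m, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(ids = rownames(m), values = unname(m)),
                         path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  } else {
    utils::write.csv(data.frame(system_id = rownames(m), m,
                                check.names = FALSE),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a full analysis report as JSON
#'
#' Bundles the pieces of a membrane-comparison analysis (systems,
#' distance matrix, dendrogram, PCA, emulation flags) together with
#' provenance (seed, tool version, timestamp) into one JSON document.
#' [read_report()] restores the numeric structures losslessly.
#'
#' @param report named list; recognised elements `systems` (data
#'   frame), `dprime` (matrix), `dendrogram_newick` (string), `pca`
#'   (an `lfer_pca`), `flags` (data frame), plus any scalars.
#' @param path output JSON path.
#' @param seed optional RNG seed recorded as provenance.
#' @export
write_report <- function(report, path, seed = NULL) {
  ser <- report
  if (!is.null(ser$dprime)) {
    ser$dprime <- list(ids = rownames(ser$dprime),
                       values = unname(as.matrix(ser$dprime)))
  }
  if (!is.null(ser$pca) && inherits(ser$pca, "lfer_pca")) {
    ser$pca <- list(
      loadings = list(rows = rownames(ser$pca$loadings),
                      cols = colnames(ser$pca$loadings),
                      values = unname(ser$pca$loadings)),
      explained_variance_fraction = ser$pca$explained_variance_fraction,
      scores = list(rows = rownames(ser$pca$scores),
                    values = unname(ser$pca$scores)))
  }
  ser$provenance <- list(tool = "pampalfer",
                         version = as.character(utils::packageVersion("pampalfer")),
                         seed = seed,
                         timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor",
                       na = "null")
  invisible(path)
}

#' Read back an analysis report written by [write_report()]
#' @param path JSON path.
#' @return Named list with matrices and data frames restored.
#' @export
read_report <- function(path) {
  rep_ <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(rep_$dprime)) {
    m <- as.matrix(rep_$dprime$values)
    dimnames(m) <- list(rep_$dprime$ids, rep_$dprime$ids)
    rep_$dprime <- m
  }
  if (!is.null(rep_$pca)) {
    ld <- as.matrix(rep_$pca$loadings$values)
    dimnames(ld) <- list(rep_$pca$loadings$rows, rep_$pca$loadings$cols)
    sc <- as.matrix(rep_$pca$scores$values)
    rownames(sc) <- rep_$pca$scores$rows
    colnames(sc) <- rep_$pca$loadings$cols
    rep_$pca <- list(loadings = ld,
                     explained_variance_fraction =
                       rep_$pca$explained_variance_fraction,
                     scores = sc)
  }
  if (!is.null(rep_$systems)) {
    rep_$systems <- as.data.frame(rep_$systems, stringsAsFactors = FALSE)
  }
  if (!is.null(rep_$flags)) {
    rep_$flags <- as.data.frame(rep_$flags, stringsAsFactors = FALSE)
  }
  rep_
}

#' Packaged coefficient compilation of PAMPA and biological systems
#'
#' Fourteen systems characterized by the solvation parameter model:
#' nine PAMPA membranes (ids 1-9; 1 = certramide skin membrane,
#' 2 = silicone/isopropyl-myristate skin membrane, 3 = porcine-brain
#' lipid, 4-9 = intestinal-absorption membranes) and five biological
#' reference processes (ids 10-14: skin permeation, water-skin
#' partition, human intestinal absorption, blood-brain partition,
#' saline-brain permeation).  Intercepts are available only for the two
#' skin-PAMPA systems fitted from raw data; literature systems carry
#' `c = NA`, which is irrelevant for D' comparisons.
#'
#' @return Data frame of systems.
#' @export
pampa_systems <- function() {
  read_systems(system.file("extdata", "pampa_systems.csv",
                           package = "pampalfer", mustWork = TRUE))
}

#' Published D' distances between PAMPA and biological systems
#'
#' The reference 5 x 8 block of published distances (biological systems
#' 10-14 vs PAMPA systems 1-8, rounded to 2 decimals), used as the
#' comparison surface for regression tests of [dprime_matrix()].
#'
#' @return Matrix with biological ids as rows and PAMPA ids as columns.
#' @export
published_distances <- function() {
  path <- system.file("extdata", "reference_dprime_published.csv",
                      package = "pampalfer", mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(raw[, -1])
  rownames(m) <- as.character(raw[[1]])
  m
}
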