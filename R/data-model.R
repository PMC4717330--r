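#' Validate a table of multistate encounter histories
#'
#' An encounter history records, for one marked individual, the observed
#' state at each study occasion: `"0"` (not detected), `"F"` (held a
#' territory in forest) or `"C"` (campground). The first non-zero entry is
#' the marking occasion. Histories are stored one row per individual in a
#' tibble with columns `id`, `ch` (the history as a string, e.g.
#' `"0F0C0"`), `sex` (`"female"`/`"male"`) and `age` (age class at marking,
#' `"ASY"`/`"SY"`).
#'
#' @param x A data frame with columns `id`, `ch`, `sex`, `age`.
#' @param n_occasions Expected history length; defaults to the common
#'   `nchar(ch)`.
#' @return A validated tibble with an added integer column `first`, the
#'   1-based marking occasion.
#' @examples
#' ms_histories(tibble::tibble(
#'   id = "b1", ch = "0F0C0", sex = "male", age = "SY"
#' ))
#' @export
ms_histories <- function(x, n_occasions = NULL) {
  x <- as_tibble(x)
  need <- c("id", "ch", "sex", "age")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("histories are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$ch <- toupper(as.character(x$ch))
  x$sex <- check_level(x$sex, .ms_sexes, "sex")
  x$age <- check_level(x$age, .ms_ages, "age")

  len <- nchar(x$ch)
  if (is.null(n_occasions)) n_occasions <- if (nrow(x)) len[1] else 0L
  if (any(len != n_occasions)) {
    stop("all encounter histories must have length ", n_occasions,
         "; offending id(s): ",
         paste(head(x$id[len != n_occasions], 3), collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^0FC]", x$ch)
  if (any(bad)) {
    stop("encounter histories may only contain 0, F, C; offending id(s): ",
         paste(head(x$id[bad], 3), collapse = ", "), call. = FALSE)
  }
  first <- regexpr("[FC]", x$ch)
  if (any(first < 0)) {
    stop("history with no detection (all zeros); offending id(s): ",
         paste(head(x$id[first < 0], 3), collapse = ", "), call. = FALSE)
  }
  x$first <- as.integer(first)
  attr(x, "n_occasions") <- as.integer(n_occasions)
  x
}

check_level <- function(v, levels, what) {
  v <- as.character(v)
  bad <- !v %in% levels
  if (any(bad)) {
    stop(what, " must be one of ", paste(levels, collapse = ", "),
         "; got: ", paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  factor(v, levels = levels)
}

## integer state matrix (0/1/2), one row per history
ch_matrix <- function(histories) {
  T <- attr(histories, "n_occasions")
  if (is.null(T)) T <- nchar(histories$ch[1])
  m <- matrix(0L, nrow(histories), T)
  if (nrow(histories) == 0) return(m)
  codes <- c("0" = 0L, "F" = 1L, "C" = 2L)
  chars <- strsplit(histories$ch, "", fixed = TRUE)
  for (i in seq_len(nrow(histories))) m[i, ] <- codes[chars[[i]]]
  m
}

matrix_ch <- function(m) {
  apply(m, 1, function(r) paste(c("0", "F", "C")[r + 1L], collapse = ""))
}

#' Read encounter histories from a MARK-style .inp file
#'
#' The reader accepts the digit-coded multistate dialect: optional
#' `/* ... */` comments, one record per statement terminated by `";"`,
#' consisting of an encounter string over `{0, 1, 2}` (0 = not detected,
#' 1 = F, 2 = C) followed by one non-negative frequency per group. Groups
#' are, in order: ASY female, SY female, ASY male, SY male. A frequency
#' greater than one is expanded into that many identical individuals.
#'
#' @param path Path to the `.inp` file.
#' @param n_occasions Expected number of occasions (optional check).
#' @return A tibble of encounter histories (see [ms_histories()]).
#' @seealso [write_inp()]
#' @export
read_inp <- function(path, n_occasions = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", " ", txt)  # strip comments (non-greedy)
  stmts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  stmts <- stmts[grepl("\\S", stmts)]
  groups <- inp_groups()
  rows <- vector("list", length(stmts))
  for (i in seq_along(stmts)) {
    tok <- strsplit(trimws(stmts[i]), "\\s+")[[1]]
    if (length(tok) != 1 + nrow(groups)) {
      stop("malformed .inp record ", i, ": expected an encounter string and ",
           nrow(groups), " group frequencies, got ", length(tok),
           " fields", call. = FALSE)
    }
    enc <- tok[1]
    if (grepl("[^012]", enc)) {
      stop("malformed .inp record ", i, ": encounter string '", enc,
           "' contains codes other than 0/1/2", call. = FALSE)
    }
    freq <- suppressWarnings(as.integer(tok[-1]))
    if (any(is.na(freq)) || any(freq < 0)) {
      stop("malformed .inp record ", i, ": bad group frequencies",
           call. = FALSE)
    }
    ch <- chartr("012", "0FC", enc)
    g <- rep(seq_len(nrow(groups)), freq)
    rows[[i]] <- tibble(
      ch = rep(ch, length(g)),
      sex = groups$sex[g], age = groups$age[g]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), ch = character(),
                  sex = character(), age = character())
  } else {
    out$id <- sprintf("ind%04d", seq_len(nrow(out)))
  }
  ms_histories(out[, c("id", "ch", "sex", "age")], n_occasions = n_occasions)
}

inp_groups <- function() {
  tibble(sex = rep(.ms_sexes, each = 2), age = rep(.ms_ages, 2))[c(1, 2, 3, 4), ]
}

#' Write encounter histories to a MARK-style .inp file
#'
#' Identical histories within a sex-by-age group are collapsed to a single
#' record with a frequency count. Group column order is ASY female,
#' SY female, ASY male, SY male (documented in a header comment).
#'
#' @param histories A tibble of encounter histories (see [ms_histories()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(histories, path) {
  histories <- ms_histories(histories)
  groups <- inp_groups()
  header <- paste0(
    "/* multistate encounter histories: 0 = not seen, 1 = F, 2 = C;",
    " groups: ASY-female SY-female ASY-male SY-male */")
  lines <- header
  if (nrow(histories) > 0) {
    counts <- dplyr::count(histories, .data$ch, .data$sex, .data$age)
    wide <- tidyr::pivot_wider(
      dplyr::mutate(counts, grp = paste(.data$age, .data$sex, sep = ".")),
      id_cols = "ch", names_from = "grp", values_from = "n", values_fill = 0L)
    grp_names <- paste(groups$age, groups$sex, sep = ".")
    for (g in grp_names) if (!g %in% names(wide)) wide[[g]] <- 0L
    enc <- chartr("0FC", "012", wide$ch)
    freq <- as.matrix(wide[, grp_names])
    lines <- c(lines, paste0(enc, " ", apply(freq, 1, paste, collapse = " "), ";"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an annual covariate table
#'
#' Reads a CSV with one row per study year. A `year` column is required;
#' recognised covariate columns are `soi`, `ndvi_west`, `ndvi_east`,
#' `rain`, `temp`, `density_F`, `density_C`, `fledge_F`, `fledge_C`.
#' Habitat densities must be non-negative integers.
#'
#' @param path Path to the CSV file.
#' @param required Character vector of columns that must be present
#'   (besides `year`).
#' @return A tibble ordered by year.
#' @export
read_covariates <- function(path, required = character()) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  validate_covariates(x, required)
}

validate_covariates <- function(x, required = character()) {
  x <- as_tibble(x)
  known <- c("soi", "ndvi_west", "ndvi_east", "rain", "temp",
             "density_F", "density_C", "fledge_F", "fledge_C")
  miss <- setdiff(c("year", required), names(x))
  if (length(miss) > 0) {
    stop("covariate table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyNA(x$year) || anyDuplicated(x$year)) {
    stop("covariate table must have one complete record per year",
         call. = FALSE)
  }
  for (d in intersect(c("density_F", "density_C"), names(x))) {
    v <- x[[d]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop("column ", d, " must contain non-negative integer territory counts",
           call. = FALSE)
    }
  }
  for (f in intersect(c("fledge_F", "fledge_C"), names(x))) {
    if (any(x[[f]] < 0)) stop("column ", f, " must be non-negative", call. = FALSE)
  }
  extra <- setdiff(names(x), c("year", known))
  if (length(extra) > 0) {
    stop("unrecognised covariate column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(x, .data$year)
}

#' Annual territory densities and fledging success for the redstart study
#'
#' Returns the published annual covariate table for the two-habitat
#' American redstart study system (2001-2011): territory counts and mean
#' fledging success per habitat (F = forest, C = campground).
#'
#' @return A tibble with columns `year`, `density_F`, `density_C`,
#'   `fledge_F`, `fledge_C`.
#' @export
redstart_covariates <- function() {
  read_covariates(system.file("extdata", "redstart_annual.csv",
                              package = "msmark", mustWork = TRUE))
}

#' Standardize annual covariates
#'
#' Z-scores each covariate column (mean 0, SD 1 over the study years, using
#' the n-1 sample SD), as is conventional before entering annual covariates
#' into link-scale models. The centering and scaling constants are stored
#' as attributes so the transformation can be inverted with
#' [destandardize_covariates()].
#'
#' @param x A covariate tibble with a `year` column.
#' @param cols Columns to standardize; default all except `year`.
#' @return The tibble with standardized columns and attributes `center`
#'   and `scale`.
#' @examples
#' z <- standardize_covariates(redstart_covariates())
#' colMeans(z[-1]) # ~0
#' @export
standardize_covariates <- function(x, cols = NULL) {
  x <- as_tibble(x)
  if (is.null(cols)) cols <- setdiff(names(x), "year")
  center <- scale <- setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    v <- x[[cl]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      stop("cannot standardize zero-variance column: ", cl, call. = FALSE)
    }
    center[cl] <- mean(v)
    scale[cl] <- s
    x[[cl]] <- (v - center[cl]) / s
  }
  attr(x, "center") <- center
  attr(x, "scale") <- scale
  x
}

#' @rdname standardize_covariates
#' @export
destandardize_covariates <- function(x) {
  center <- attr(x, "center")
  scale <- attr(x, "scale")
  if (is.null(center)) stop("no standardization attributes found", call. = FALSE)
  for (cl in names(center)) x[[cl]] <- x[[cl]] * scale[cl] + center[cl]
  attr(x, "center") <- NULL
  attr(x, "scale") <- NULL
  x
}
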