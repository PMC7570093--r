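#' Moisture-series thermal transition dataset
#'
#' Container for one sample's DSC-derived transition temperatures:
#' glass transitions Tg(ws) from the unfreezable-water domain, freezing
#' points Tm(ws) from the freezable domain, and replicate observations
#' of the maximally freeze-concentrated transitions Tg' and Tm'.
#'
#' @param sample_id Sample identifier (character scalar).
#' @param tg_points Data frame with columns `ws`, `tg` (degC), or NULL.
#' @param tm_points Data frame with columns `ws`, `tm` (degC), or NULL.
#' @param tg_prime_obs,tm_prime_obs Numeric vectors of replicate
#'   observations (degC); may be empty.
#' @param composition Optional [composition()].
#' @return A list of class `"thermal_dataset"`.
#' @export
thermal_dataset <- function(sample_id, tg_points = NULL, tm_points = NULL,
                            tg_prime_obs = numeric(), tm_prime_obs = numeric(),
                            composition = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  chk <- function(df, val) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(c("ws", val) %in% names(df))) {
      stop(sprintf("points table needs columns 'ws' and '%s'", val),
           call. = FALSE)
    }
    if (anyNA(df$ws) || any(df$ws < 0) || any(df$ws > 1)) {
      stop("all ws must lie in [0, 1]", call. = FALSE)
    }
    df[, c("ws", val)]
  }
  if (!is.null(composition)) stopifnot(inherits(composition, "composition"))
  structure(list(sample_id = sample_id,
                 tg_points = chk(tg_points, "tg"),
                 tm_points = chk(tm_points, "tm"),
                 tg_prime_obs = as.numeric(tg_prime_obs),
                 tm_prime_obs = as.numeric(tm_prime_obs),
                 composition = composition),
            class = "thermal_dataset")
}

#' @export
print.thermal_dataset <- function(x, ...) {
  cat(sprintf("Thermal dataset '%s': %d Tg points, %d Tm points, %d Tg' obs, %d Tm' obs\n",
              x$sample_id,
              if (is.null(x$tg_points)) 0L else nrow(x$tg_points),
              if (is.null(x$tm_points)) 0L else nrow(x$tm_points),
              length(x$tg_prime_obs), length(x$tm_prime_obs)))
  invisible(x)
}

# long-format CSV dialect: sample_id, ws, kind, temperature_c
.thermal_kinds <- c("tg", "tm", "tg_prime", "tm_prime")

#' Read a thermal dataset from CSV
#'
#' Long format with columns `sample_id, ws, kind, temperature_c` where
#' `kind` is one of `tg, tm, tg_prime, tm_prime`.  Unicode minus signs
#' are normalized to ASCII on input.
#'
#' @param path CSV file path.
#' @param sample_id Optional: restrict to one sample; default uses the
#'   single sample present (error if several).
#' @return A [thermal_dataset()].
#' @export
read_thermal_csv <- function(path, sample_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  need <- c("sample_id", "ws", "kind", "temperature_c")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(sprintf("thermal CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  dash <- function(x) gsub("−", "-", x)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(dash(raw[[col]])))
    x <- raw[[col]]
    bad <- which(is.na(v) & !is.na(x) & nzchar(x) & x != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   raw[[col]][bad[1]], col, bad[1]), call. = FALSE)
    }
    v
  }
  raw$ws <- num("ws"); raw$temperature_c <- num("temperature_c")
  badk <- which(!raw$kind %in% .thermal_kinds)
  if (length(badk)) {
    stop(sprintf("invalid kind '%s' at data row %d (expected one of %s)",
                 raw$kind[badk[1]], badk[1],
                 paste(.thermal_kinds, collapse = ", ")), call. = FALSE)
  }
  if (is.null(sample_id)) {
    ids <- unique(raw$sample_id)
    if (length(ids) != 1L) {
      stop("file contains several samples; pass sample_id", call. = FALSE)
    }
    sample_id <- ids
  }
  d <- raw[raw$sample_id == sample_id, ]
  pick <- function(k, val) {
    sub <- d[d$kind == k, ]
    if (!nrow(sub)) return(NULL)
    stats::setNames(data.frame(sub$ws, sub$temperature_c), c("ws", val))
  }
  thermal_dataset(sample_id,
                  tg_points = pick("tg", "tg"),
                  tm_points = pick("tm", "tm"),
                  tg_prime_obs = d$temperature_c[d$kind == "tg_prime"],
                  tm_prime_obs = d$temperature_c[d$kind == "tm_prime"])
}

#' Write a thermal dataset to CSV
#'
#' Inverse of [read_thermal_csv()]; full-precision, ASCII minus.
#'
#' @param data A [thermal_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermal_csv <- function(data, path) {
  stopifnot(inherits(data, "thermal_dataset"))
  rows <- list()
  if (!is.null(data$tg_points)) {
    rows <- c(rows, list(data.frame(ws = data$tg_points$ws, kind = "tg",
                                    temperature_c = data$tg_points$tg)))
  }
  if (!is.null(data$tm_points)) {
    rows <- c(rows, list(data.frame(ws = data$tm_points$ws, kind = "tm",
                                    temperature_c = data$tm_points$tm)))
  }
  if (length(data$tg_prime_obs)) {
    rows <- c(rows, list(data.frame(ws = NA_real_, kind = "tg_prime",
                                    temperature_c = data$tg_prime_obs)))
  }
  if (length(data$tm_prime_obs)) {
    rows <- c(rows, list(data.frame(ws = NA_real_, kind = "tm_prime",
                                    temperature_c = data$tm_prime_obs)))
  }
  out <- do.call(rbind, rows)
  out <- cbind(sample_id = data$sample_id, out)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a flat parameter configuration
#'
#' Parameter sets serialize to a flat key-value YAML mapping with keys
#' `tgs, k, tgw` (Gordon-Taylor) and `e, b, tw, beta, lambda_w` (Chen).
#'
#' @param gt A [gt_params()] or NULL.
#' @param chen A [chen_params()] or NULL.
#' @param path File path.
#' @param extra Optional named list of additional scalar entries (e.g.
#'   `r_squared`).
#' @return `path`, invisibly.
#' @export
write_params <- function(path, gt = NULL, chen = NULL, extra = NULL) {
  out <- list()
  if (!is.null(gt)) { stopifnot(inherits(gt, "gt_params")); out <- c(out, unclass(gt)) }
  if (!is.null(chen)) { stopifnot(inherits(chen, "chen_params")); out <- c(out, unclass(chen)) }
  if (!is.null(extra)) out <- c(out, extra)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @return For `read_params`: a list with elements `gt` and/or `chen`
#'   (whichever key sets are present) plus any extra entries under
#'   `extra`.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  out <- list()
  if (all(c("tgs", "k") %in% names(x))) {
    out$gt <- gt_params(x$tgs, x$k, tgw = if (is.null(x$tgw)) -135 else x$tgw)
  }
  if (all(c("e", "b") %in% names(x))) {
    out$chen <- chen_params(x$e, x$b,
                            tw = if (is.null(x$tw)) 0 else x$tw,
                            beta = if (is.null(x$beta)) 1860 else x$beta,
                            lambda_w = if (is.null(x$lambda_w)) 18.015 else x$lambda_w)
  }
  known <- c("tgs", "k", "tgw", "e", "b", "tw", "beta", "lambda_w")
  extra <- x[setdiff(names(x), known)]
  if (length(extra)) out$extra <- extra
  out
}
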