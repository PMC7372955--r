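#' Read and write gridded flow-field tables
#'
#' The on-disk exchange format is a UTF-8 comma-delimited table with the
#' exact header
#' `depth_mm,lateral_mm,u_depth_m_s,u_lateral_m_s,k_cm2_s2,eps_cm2_s3`
#' (an optional trailing `gas_fraction` column is preserved), one row per
#' grid cell in row-major order with the lateral coordinate varying
#' fastest. Externally produced CFD exports in this format can be analysed
#' by the same pipeline as synthetic fields. Values are written in full
#' (17 significant digit) precision so a write/read round trip is
#' bit-exact.
#'
#' @param field A [pbr_flow_field] object.
#' @param path File path.
#' @param geom Optional [make_geometry()] object; when supplied the culture
#'   mask is rebuilt from the geometry, otherwise every cell is treated as
#'   culture.
#' @return `read_field_table()` returns a [pbr_flow_field];
#'   `write_field_table()` returns `path` invisibly.
#' @export
write_field_table <- function(field, path) {
  stopifnot(inherits(field, "pbr_flow_field"))
  nd <- length(field$depth); nl <- length(field$lateral)
  df <- data.frame(
    depth_mm   = rep(field$depth, each = nl),
    lateral_mm = rep(field$lateral, times = nd),
    u_depth_m_s   = as.vector(t(field$u_depth)),
    u_lateral_m_s = as.vector(t(field$u_lateral)),
    k_cm2_s2   = as.vector(t(field$k)),
    eps_cm2_s3 = as.vector(t(field$eps)))
  if (!is.null(field$gas_fraction))
    df$gas_fraction <- as.vector(t(field$gas_fraction))
  txt <- vapply(df, function(x) sprintf("%.17g", x), character(nrow(df)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_field_table
#' @export
read_field_table <- function(path, geom = NULL) {
  required <- c("depth_mm", "lateral_mm", "u_depth_m_s", "u_lateral_m_s",
                "k_cm2_s2", "eps_cm2_s3")
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("field table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- lapply(df, function(x) suppressWarnings(as.numeric(x)))
  for (nm in names(num)) {
    bad <- which(is.na(num[[nm]]) & !is.na(df[[nm]]) & df[[nm]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data row %d", nm, bad[1]),
           call. = FALSE)
  }
  num <- as.data.frame(num, check.names = FALSE)
  dep <- sort(unique(num$depth_mm)); lat <- sort(unique(num$lateral_mm))
  nd <- length(dep); nl <- length(lat)
  if (nrow(num) != nd * nl)
    stop(sprintf(paste0("field table is not a complete rectangular grid: ",
                        "%d rows for %d x %d coordinates"),
                 nrow(num), nd, nl), call. = FALSE)
  h_d <- if (nd > 1) diff(dep) else 1
  h_l <- if (nl > 1) diff(lat) else 1
  if (max(abs(h_d - h_d[1])) > 1e-9 * max(abs(dep), 1) ||
      max(abs(h_l - h_l[1])) > 1e-9 * max(abs(lat), 1) ||
      abs(h_d[1] - h_l[1]) > 1e-9 * max(h_d[1], h_l[1]))
    stop("field table grid is not uniform with equal spacing in both axes",
         call. = FALSE)
  ord <- order(num$depth_mm, num$lateral_mm)
  num <- num[ord, , drop = FALSE]
  as_mat <- function(x) matrix(x, nd, nl, byrow = TRUE)
  if (is.null(geom)) {
    mask <- matrix(TRUE, nd, nl)
    geom <- make_geometry("plain", outer_radius = max(abs(c(dep, lat))) + h_d[1])
  } else {
    mask <- matrix(in_culture(geom, rep(dep, times = nl),
                              rep(lat, each = nd)), nd, nl)
  }
  kmat <- as_mat(num$k_cm2_s2); emat <- as_mat(num$eps_cm2_s3)
  if (any(kmat[mask] < 0) || any(emat[mask] <= 0))
    stop("field table has k < 0 or eps <= 0 inside the culture region",
         call. = FALSE)
  gf <- if ("gas_fraction" %in% names(num)) as_mat(num$gas_fraction) else NULL
  new_flow_field(geom, dep, lat, h_d[1],
                 as_mat(num$u_depth_m_s), as_mat(num$u_lateral_m_s),
                 kmat, emat, mask, gf)
}
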