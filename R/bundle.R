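#' Write a raw scan or basis set as an FID bundle
#'
#' A bundle is a directory holding `manifest.json` (acquisition parameters,
#' labels, provenance, seed, and ground-truth concentrations when synthetic)
#' plus one CSV per FID with header `index,re,im`.
#'
#' @param x A `raw_scan` or [basis_set].
#' @param path Directory to create.
#' @return Invisibly, the manifest as a list.
#' @export
write_bundle <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  write_fid_csv <- function(samples, file) {
    # %.17g keeps doubles exactly through the text round trip
    lines <- c("index,re,im",
               sprintf("%d,%.17g,%.17g", seq_along(samples) - 1L,
                       Re(samples), Im(samples)))
    writeLines(lines, file.path(path, file))
  }
  acq_list <- function(acq) acq[c("transmitter_mhz", "center_ppm", "sw_hz",
                                  "n_points", "te_ms", "tr_ms",
                                  "n_transients", "sequence_tag",
                                  "editing_ppm")]
  if (inherits(x, "raw_scan")) {
    files <- list()
    for (lab in names(x$transients)) {
      for (i in seq_along(x$transients[[lab]])) {
        f <- sprintf("%s_%03d.csv", lab, i)
        write_fid_csv(x$transients[[lab]][[i]]$samples, f)
        files[[lab]] <- c(files[[lab]], f)
      }
    }
    write_fid_csv(x$water$samples, "WATER.csv")
    manifest <- list(kind = "scan", acq = acq_list(x$acq),
                     labels = names(x$transients),
                     n_per_label = lengths(x$transients),
                     subject_id = x$subject_id, scan_id = x$scan_id,
                     sequence_tag = x$sequence_tag, seed = x$seed,
                     synthetic = TRUE, truth = as.list(x$truth),
                     files = files, water_file = "WATER.csv")
  } else if (inherits(x, "basis_set")) {
    files <- character()
    for (i in seq_along(x$names)) {
      f <- sprintf("basis_%s.csv", x$names[i])
      write_fid_csv(x$fids[, i], f)
      files <- c(files, f)
    }
    manifest <- list(kind = "basis", basis = TRUE, acq = acq_list(x$acq),
                     names = x$names, mm_names = x$mm_names,
                     target = x$target, files = files)
  } else {
    stop("write_bundle handles raw_scan and basis_set objects")
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_fid_csv <- function(file, expect_n) {
  d <- utils::read.csv(file)
  if (!all(c("index", "re", "im") %in% names(d))) {
    stop("malformed FID table (need index,re,im columns): ", file)
  }
  if (nrow(d) != expect_n) {
    stop(sprintf("%s has %d samples, manifest expects %d", file, nrow(d),
                 expect_n))
  }
  complex(real = d$re, imaginary = d$im)
}

#' Read an FID bundle written by [write_bundle]
#'
#' Validates the manifest against the files on disk; violations (missing
#' files, truncated tables, unknown sequence tags) produce errors naming the
#' offending field or file.
#'
#' @param path Bundle directory.
#' @return A `raw_scan` or [basis_set], per the manifest `kind`.
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  a <- man$acq
  if (is.null(a$sequence_tag) ||
      !a$sequence_tag %in% c("HERMES80", "MEGA120")) {
    stop("manifest field acq$sequence_tag is missing or unknown: ",
         a$sequence_tag %||% "<missing>")
  }
  acq <- acq_params(transmitter_mhz = a$transmitter_mhz,
                    center_ppm = a$center_ppm, sw_hz = a$sw_hz,
                    n_points = a$n_points, te_ms = a$te_ms, tr_ms = a$tr_ms,
                    n_transients = a$n_transients,
                    sequence_tag = a$sequence_tag,
                    editing_ppm = unlist(a$editing_ppm))
  if (identical(man$kind, "scan")) {
    labels <- unlist(man$labels)
    expected <- subexp_labels(acq$sequence_tag)
    if (!setequal(labels, expected)) {
      stop("manifest labels ", paste(labels, collapse = "/"),
           " do not match sequence ", acq$sequence_tag)
    }
    transients <- lapply(stats::setNames(labels, labels), function(lab) {
      fl <- unlist(man$files[[lab]])
      lapply(fl, function(f) {
        fid(read_fid_csv(file.path(path, f), acq$n_points), acq, lab)
      })
    })
    water <- fid(read_fid_csv(file.path(path, man$water_file),
                              acq$n_points), acq, "WATER")
    structure(list(transients = transients, water = water,
                   truth = unlist(man$truth), subject_id = man$subject_id,
                   scan_id = man$scan_id, sequence_tag = man$sequence_tag,
                   acq = acq, seed = man$seed), class = "raw_scan")
  } else if (identical(man$kind, "basis")) {
    nms <- unlist(man$names)
    fids <- vapply(unlist(man$files), function(f) {
      read_fid_csv(file.path(path, f), acq$n_points)
    }, complex(acq$n_points))
    basis_set(nms, unname(fids), acq, man$target,
              mm_names = unlist(man$mm_names) %||% character())
  } else {
    stop("manifest field kind must be 'scan' or 'basis', got: ",
         man$kind %||% "<missing>")
  }
}
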