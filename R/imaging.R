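# Encoding masked hemoglobin deltas as 5x10 grayscale frames.
#
# Each of the 22 channels owns a 1x2-pixel block on a 5-row x 10-column grid.
# Single-species frames (oxy, deoxy) fill the whole block with that channel's
# code; mixed (OD) frames put the oxy code in the left pixel and the deoxy
# code in the right pixel. Six grid cells are unassigned background (code 0).

#' Grayscale coding scheme
#'
#' 256 gradations, 255 = white (scope maximum), 0 = black (scope minimum).
#' The normalization scope says over which set of deltas the min/max are
#' taken.
#'
#' @param scope `"per-subject"` (min/max over all unmasked rest+clench deltas
#'   of the subject, per Hb species; the default), `"per-frame"` or
#'   `"global"` (cohort-wide, supplied explicitly via `bounds`).
#' @return an object of class `grayscale_scheme`.
#' @export
grayscale_scheme <- function(scope = c("per-subject", "per-frame", "global")) {
  structure(list(levels = 256L, max_code = 255L, min_code = 0L,
                 scope = match.arg(scope)),
            class = "grayscale_scheme")
}

#' Default channel-to-pixel layout
#'
#' 22 non-overlapping 1x2 blocks on the 5x10 grid, following the 3x5 optode
#' grid: rows of 4/5/4/5/4 channels (Ch1-4, Ch5-9, Ch10-13, Ch14-18,
#' Ch19-22); 5-channel rows span all 10 columns, 4-channel rows leave one
#' blank background column on each side.
#'
#' @return an object of class `channel_layout`: data.frame with columns
#'   `channel`, `row`, `col_start`, `region`.
#' @export
default_channel_layout <- function() {
  row <- rep(1:5, times = c(4, 5, 4, 5, 4))
  col_start <- c(c(2, 4, 6, 8), c(1, 3, 5, 7, 9), c(2, 4, 6, 8),
                 c(1, 3, 5, 7, 9), c(2, 4, 6, 8))
  layout <- data.frame(channel = 1:22, row = row, col_start = col_start,
                       region = channel_regions())
  validate_layout(layout)
}

validate_layout <- function(layout) {
  if (nrow(layout) != 22L) nc_stop("layout must define 22 channels",
                                   "nc_layout_error")
  if (any(layout$row < 1 | layout$row > 5) ||
      any(layout$col_start < 1 | layout$col_start + 1 > 10)) {
    nc_stop("channel blocks must lie inside the 5x10 grid", "nc_layout_error")
  }
  occ <- matrix(0L, 5, 10)
  for (i in seq_len(22)) {
    cells <- cbind(layout$row[i], layout$col_start[i] + 0:1)
    occ[cells] <- occ[cells] + 1L
  }
  if (any(occ > 1L)) nc_stop("channel blocks overlap", "nc_layout_error")
  class(layout) <- c("channel_layout", "data.frame")
  layout
}

#' Write / read a channel layout as JSON
#'
#' The on-disk form is `{"channels": {"1": {"row": r, "col_start": c}, ...},
#' "regions": {...}}` so the pixel mapping can be corrected without code
#' changes.
#'
#' @param layout a `channel_layout`.
#' @param path JSON file path.
#' @return `write_channel_layout`: the path, invisibly;
#'   `read_channel_layout`: a `channel_layout`.
#' @export
write_channel_layout <- function(layout, path) {
  chans <- lapply(seq_len(nrow(layout)), function(i) {
    list(row = layout$row[i], col_start = layout$col_start[i])
  })
  names(chans) <- as.character(layout$channel)
  regions <- as.list(stats::setNames(layout$region,
                                     as.character(layout$channel)))
  jsonlite::write_json(list(channels = chans, regions = regions), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_channel_layout
#' @export
read_channel_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- as.integer(names(j$channels))
  layout <- data.frame(
    channel = ch,
    row = vapply(j$channels, function(x) as.integer(x$row), integer(1)),
    col_start = vapply(j$channels, function(x) as.integer(x$col_start),
                       integer(1)),
    region = unlist(j$regions)[as.character(ch)],
    row.names = NULL
  )
  validate_layout(layout[order(layout$channel), ])
}

#' Scale delta values to integer grayscale codes
#'
#' `code = round_half_up(255 * (v - lo) / (hi - lo))`, clipped to `[0, 255]`.
#' When `hi == lo` (degenerate scope) every value maps to mid-gray 127. `NA`
#' values (masked samples) stay `NA`; any other non-finite value is an
#' internal error (it should have been masked upstream).
#'
#' @param v numeric values.
#' @param lo,hi scope minimum / maximum; `hi >= lo`, both finite.
#' @return integer codes in `[0, 255]` (NA preserved).
#' @export
scale_to_gray <- function(v, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi < lo) {
    nc_stop("gray bounds must be finite with hi >= lo", "nc_parameter_error")
  }
  if (any(!is.finite(v) & !is.na(v))) {
    nc_stop("non-finite delta reached the encoder unmasked",
            "nc_internal_error")
  }
  if (hi == lo) {
    out <- rep(127L, length(v))
    out[is.na(v)] <- NA_integer_
    return(out)
  }
  code <- round_half_up(255 * (v - lo) / (hi - lo))
  as.integer(pmin(255, pmax(0, code)))
}

# pixel linear indices (in a 5x10 matrix) of each channel's left/right pixel
layout_pixel_index <- function(layout) {
  left <- (layout$col_start - 1L) * 5L + layout$row
  right <- layout$col_start * 5L + layout$row
  list(left = left, right = right)
}

#' Render one grayscale frame
#'
#' @param oxy_codes,deoxy_codes integer codes (length 22, `NA` = missing);
#'   `oxy_codes` is required for modalities `"oxy"` and `"od"`, `deoxy_codes`
#'   for `"deoxy"` and `"od"`.
#' @param layout a `channel_layout`.
#' @param modality `"oxy"`, `"deoxy"` or `"od"`.
#' @return list with `pixels` (5x10 integer matrix, background 0, missing
#'   blocks `NA`), `valid` (no required channel missing) and `reason`.
#' @export
render_frame <- function(oxy_codes = NULL, deoxy_codes = NULL, layout,
                         modality = c("oxy", "deoxy", "od")) {
  modality <- match.arg(modality)
  need <- switch(modality, oxy = list(oxy_codes), deoxy = list(deoxy_codes),
                 od = list(oxy_codes, deoxy_codes))
  if (any(vapply(need, is.null, logical(1))) ||
      any(vapply(need, length, integer(1)) != 22L)) {
    nc_stop("modality requires 22 codes per needed Hb species",
            "nc_layout_error")
  }
  px <- layout_pixel_index(layout)
  img <- matrix(0L, 5, 10)
  if (modality == "oxy") {
    img[px$left] <- oxy_codes; img[px$right] <- oxy_codes
  } else if (modality == "deoxy") {
    img[px$left] <- deoxy_codes; img[px$right] <- deoxy_codes
  } else {
    img[px$left] <- oxy_codes; img[px$right] <- deoxy_codes
  }
  missing <- anyNA(unlist(need))
  list(pixels = img, valid = !missing,
       reason = if (missing) "missing channel" else NA_character_)
}

#' Decode channel codes from a rendered frame
#'
#' Inverse of [render_frame()] for round-trip checks: reads each channel's
#' block back. For single-species frames both block pixels are checked to be
#' equal.
#'
#' @param pixels 5x10 integer matrix.
#' @param layout a `channel_layout`.
#' @param modality frame modality.
#' @return for `"oxy"`/`"deoxy"`: integer(22); for `"od"`: list with `oxy`
#'   and `deoxy` integer(22).
#' @export
decode_frame <- function(pixels, layout, modality = c("oxy", "deoxy", "od")) {
  modality <- match.arg(modality)
  px <- layout_pixel_index(layout)
  left <- pixels[px$left]
  right <- pixels[px$right]
  if (modality == "od") return(list(oxy = left, deoxy = right))
  if (any(left != right, na.rm = TRUE)) {
    nc_stop("single-species frame has unequal block pixels", "nc_layout_error")
  }
  left
}

# per-subject scope bounds: min/max of unmasked rest+clench deltas per species
subject_gray_bounds <- function(ed) {
  lapply(list(oxy = "oxy", deoxy = "deoxy"), function(sp) {
    vals <- c(delta_values(ed, sp, "rest"), delta_values(ed, sp, "clench"))
    r <- range(vals, na.rm = TRUE)
    c(lo = r[1], hi = r[2])
  })
}

#' Build the candidate frame set for one subject
#'
#' One candidate frame per retained 10 Hz sample (600 rest + 550 clench at
#' stride 1) per requested modality. Frames with any required channel masked
#' at that timepoint are flagged invalid; OD validity is the intersection of
#' oxy and deoxy validity at the sample.
#'
#' @param ed an `epoch_deltas` (masked).
#' @param layout a `channel_layout`.
#' @param scheme a [grayscale_scheme()].
#' @param modalities subset of `c("oxy", "deoxy", "od")`.
#' @param stride keep every `stride`-th sample within each window (desk-scale
#'   runs use stride > 1; 1 reproduces the full 10 Hz frame set).
#' @param bounds optional explicit scope bounds, a list
#'   `list(oxy = c(lo, hi), deoxy = c(lo, hi))` (required for
#'   `scope = "global"`).
#' @return an object of class `hb_image_set`: `pixels` (5 x 10 x K integer
#'   array over all candidates, all modalities stacked), `meta` (data.frame
#'   `subject`, `modality`, `label`, `window`, `sample_index`, `valid`) and
#'   `counts` (candidates / valid per modality).
#' @export
build_image_set <- function(ed, layout = default_channel_layout(),
                            scheme = grayscale_scheme(),
                            modalities = c("oxy", "deoxy", "od"),
                            stride = 1L, bounds = NULL) {
  stopifnot(inherits(ed, "epoch_deltas"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (scheme$scope == "global" && is.null(bounds)) {
    nc_stop("global scope requires explicit bounds", "nc_parameter_error")
  }
  if (scheme$scope == "per-subject" && is.null(bounds)) {
    bounds <- subject_gray_bounds(ed)
  }
  px <- layout_pixel_index(layout)

  # per species: codes matrix (22 x n_kept) per window, NA where masked
  enc <- lapply(list(oxy = "oxy", deoxy = "deoxy"), function(sp) {
    lapply(list(rest = "rest", clench = "clench"), function(win) {
      d <- delta_values(ed, sp, win)
      keep <- seq(1L, nrow(d), by = stride)
      d <- d[keep, , drop = FALSE]
      codes <- if (scheme$scope == "per-frame") {
        t(apply(d, 1, function(r) {
          rng <- suppressWarnings(range(r, na.rm = TRUE))
          if (!all(is.finite(rng))) rep(NA_integer_, length(r))
          else scale_to_gray(r, rng[1], rng[2])
        }))
      } else {
        b <- bounds[[sp]]
        matrix(scale_to_gray(as.vector(d), b[[1]], b[[2]]), nrow = nrow(d))
      }
      list(codes = t(codes), sample_index = keep)  # 22 x n_kept
    })
  })

  pixel_list <- list(); meta_list <- list()
  for (mod in modalities) {
    for (win in c("rest", "clench")) {
      oxy_c <- enc$oxy[[win]]$codes
      deoxy_c <- enc$deoxy[[win]]$codes
      nk <- ncol(oxy_c)
      flat <- matrix(0L, 50L, nk)
      if (mod == "oxy") {
        flat[px$left, ] <- oxy_c; flat[px$right, ] <- oxy_c
        valid <- colSums(is.na(oxy_c)) == 0L
      } else if (mod == "deoxy") {
        flat[px$left, ] <- deoxy_c; flat[px$right, ] <- deoxy_c
        valid <- colSums(is.na(deoxy_c)) == 0L
      } else {
        flat[px$left, ] <- oxy_c; flat[px$right, ] <- deoxy_c
        valid <- colSums(is.na(oxy_c)) == 0L & colSums(is.na(deoxy_c)) == 0L
      }
      pixel_list[[paste(mod, win)]] <- flat
      meta_list[[paste(mod, win)]] <- data.frame(
        subject = ed$subject_id, modality = mod,
        label = if (win == "rest") "rest" else "clench",
        window = win, sample_index = enc$oxy[[win]]$sample_index,
        valid = valid)
    }
  }
  flat_all <- do.call(cbind, pixel_list)
  meta <- do.call(rbind, c(meta_list, list(make.row.names = FALSE)))
  counts <- do.call(rbind, lapply(modalities, function(mod) {
    sel <- meta$modality == mod
    data.frame(modality = mod, candidates = sum(sel),
               valid = sum(meta$valid[sel]))
  }))
  structure(list(pixels = array(flat_all, dim = c(5L, 10L, ncol(flat_all))),
                 meta = meta, counts = counts),
            class = "hb_image_set")
}

#' Combine per-subject image sets into one cohort set
#'
#' @param sets list of `hb_image_set` objects.
#' @return a single `hb_image_set` with concatenated frames, metadata and
#'   summed counts.
#' @export
combine_image_sets <- function(sets) {
  pix <- do.call(cbind, lapply(sets, function(s) {
    matrix(s$pixels, nrow = 50L)
  }))
  meta <- do.call(rbind, c(lapply(sets, `[[`, "meta"),
                           list(make.row.names = FALSE)))
  counts <- do.call(rbind, lapply(sets, `[[`, "counts"))
  counts <- stats::aggregate(cbind(candidates, valid) ~ modality, counts, sum)
  structure(list(pixels = array(pix, dim = c(5L, 10L, ncol(pix))),
                 meta = meta, counts = counts),
            class = "hb_image_set")
}

#' Squash-resize a frame to a square
#'
#' Aspect ratio is ignored (squash). Nearest-neighbor keeps channel blocks
#' piecewise-constant; bilinear is available for sensitivity checks.
#'
#' @param pixels 5x10 numeric/integer matrix.
#' @param side output side length (default 256).
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return `side` x `side` numeric matrix.
#' @export
resize_squash <- function(pixels, side = 256L, method = c("nearest",
                                                          "bilinear")) {
  method <- match.arg(method)
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (method == "nearest") {
    ri <- floor((seq_len(side) - 1) * nr / side) + 1L
    ci <- floor((seq_len(side) - 1) * nc / side) + 1L
    return(pixels[ri, ci, drop = FALSE])
  }
  # bilinear on pixel centers
  sy <- (seq_len(side) - 0.5) * nr / side - 0.5
  sx <- (seq_len(side) - 0.5) * nc / side - 0.5
  y0 <- pmin(pmax(floor(sy), 0), nr - 1); y1 <- pmin(y0 + 1, nr - 1)
  x0 <- pmin(pmax(floor(sx), 0), nc - 1); x1 <- pmin(x0 + 1, nc - 1)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  p <- function(r, c) {   # r indexes rows (varies fastest), c columns
    matrix(pixels[cbind(rep(r, times = side) + 1L,
                        rep(c, each = side) + 1L)], side)
  }
  outer(1 - wy, 1 - wx) * p(y0, x0) + outer(1 - wy, wx) * p(y0, x1) +
    outer(wy, 1 - wx) * p(y1, x0) + outer(wy, wx) * p(y1, x1)
}

#' Export valid frames as 8-bit grayscale PNGs with an index CSV
#'
#' @param imgset an `hb_image_set`.
#' @param dir output directory.
#' @return invisibly, the index data.frame (columns `subject`, `modality`,
#'   `label`, `sample_index`, `valid`, `path`).
#' @export
write_frames_png <- function(imgset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- imgset$meta
  meta$path <- NA_character_
  for (i in which(meta$valid)) {
    fn <- sprintf("%s_%s_%s_%04d.png", meta$subject[i], meta$modality[i],
                  meta$label[i], meta$sample_index[i])
    path <- file.path(dir, fn)
    png::writePNG(imgset$pixels[, , i] / 255, path)
    meta$path[i] <- fn
  }
  idx <- meta[, c("subject", "modality", "label", "sample_index", "valid",
                  "path")]
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}
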