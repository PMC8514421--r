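#' Canonical cheliceral muscle set
#'
#' The seven muscle groups associated with the cheliceral bases that a
#' complete micro-CT measurement table must cover. Endosternite muscles,
#' when absent from a species, are represented by absent rows, not zeros.
#' @export
CHELICERAL_MUSCLES <- c(
  "anterior medial inner", "anterior median outer", "anterior outer",
  "lateral anterior", "lateral posterior", "posterior median",
  "intercheliceral sclerite"
)

#' A single micro-CT muscle measurement
#'
#' Tendon length plus shortest and longest fiber length (microns) for one
#' muscle on one side, with the cheliceral state and per-field
#' extrapolation flags (set when a detached muscle's length was
#' extrapolated to the interior carapace surface).
#'
#' @param muscle_name One of [CHELICERAL_MUSCLES].
#' @param state `"open"` or `"closed"`.
#' @param side `"L"`, `"R"`, or `"averaged"`.
#' @param tendon_um,shortest_fiber_um,longest_fiber_um Lengths, microns
#'   (> 0; `shortest_fiber_um <= longest_fiber_um`).
#' @param extrapolated Logical length 3 (tendon, shortest fiber, longest
#'   fiber) or length 1, recycled.
#' @return Object of class `muscle_measurement`.
#' @export
muscle_measurement <- function(muscle_name, state, side, tendon_um,
                               shortest_fiber_um, longest_fiber_um,
                               extrapolated = FALSE) {
  muscle_name <- match.arg(muscle_name, CHELICERAL_MUSCLES)
  state <- match.arg(state, c("open", "closed"))
  side <- match.arg(side, c("L", "R", "averaged"))
  lens <- c(tendon = tendon_um, shortest_fiber = shortest_fiber_um,
            longest_fiber = longest_fiber_um)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all lengths must be positive and finite")
  }
  if (shortest_fiber_um > longest_fiber_um) {
    stop("shortest fiber exceeds longest fiber for '", muscle_name, "'")
  }
  extrapolated <- rep_len(as.logical(extrapolated), 3L)
  names(extrapolated) <- c("tendon", "shortest_fiber", "longest_fiber")
  structure(
    list(muscle_name = muscle_name, state = state, side = side,
         tendon_um = tendon_um, shortest_fiber_um = shortest_fiber_um,
         longest_fiber_um = longest_fiber_um, extrapolated = extrapolated),
    class = "muscle_measurement"
  )
}

#' Average left and right muscle measurements
#'
#' Micro-CT measurements are taken on both sides and reported as the
#' arithmetic mean per field; extrapolation flags propagate by OR.
#'
#' @param left,right `muscle_measurement` objects for the same muscle and
#'   state on opposite sides.
#' @return A `muscle_measurement` with `side = "averaged"`.
#' @export
average_sides <- function(left, right) {
  stopifnot(inherits(left, "muscle_measurement"),
            inherits(right, "muscle_measurement"))
  if (!identical(left$muscle_name, right$muscle_name) ||
      !identical(left$state, right$state)) {
    stop("cannot average mismatched measurements: ",
         left$muscle_name, "/", left$state, " vs ",
         right$muscle_name, "/", right$state)
  }
  muscle_measurement(
    muscle_name = left$muscle_name, state = left$state, side = "averaged",
    tendon_um = mean(c(left$tendon_um, right$tendon_um)),
    shortest_fiber_um = mean(c(left$shortest_fiber_um, right$shortest_fiber_um)),
    longest_fiber_um = mean(c(left$longest_fiber_um, right$longest_fiber_um)),
    extrapolated = left$extrapolated | right$extrapolated
  )
}

#' Size-correct a length by carapace width
#'
#' Divides a raw length (microns) by the specimen's carapace width
#' (microns), giving a dimensionless ratio comparable across specimens and
#' scans. The raw ratio is returned; rendering to two decimals (half-even)
#' happens only at table-formatting time.
#'
#' @param value_um Raw length(s), microns (> 0).
#' @param carapace_width_um Carapace width, microns (> 0).
#' @return Dimensionless ratio(s).
#' @export
#' @examples
#' size_correct(91.43, 500.4) # ~0.18
size_correct <- function(value_um, carapace_width_um) {
  if (any(!is.finite(carapace_width_um)) || any(carapace_width_um <= 0)) {
    stop("carapace width must be positive")
  }
  if (any(!is.finite(value_um)) || any(value_um <= 0)) {
    stop("measurement must be positive")
  }
  value_um / carapace_width_um
}

#' Clypeus thickness ratio
#'
#' Ratio of clypeus thickness to the carapace thickness between the
#' anterior median eyes — a comparative trait of trap-jaw morphology.
#'
#' @param clypeus_um Clypeus thickness, microns (> 0).
#' @param carapace_at_AME_um Carapace thickness between the anterior
#'   median eyes, microns (> 0).
#' @return Dimensionless ratio.
#' @export
clypeus_ratio <- function(clypeus_um, carapace_at_AME_um) {
  if (any(!is.finite(clypeus_um)) || any(clypeus_um <= 0)) {
    stop("clypeus thickness must be positive")
  }
  if (any(!is.finite(carapace_at_AME_um)) || any(carapace_at_AME_um <= 0)) {
    stop("carapace thickness must be positive")
  }
  clypeus_um / carapace_at_AME_um
}

#' Build the size-corrected muscle table
#'
#' Produces the wide muscle table: for each of the seven cheliceral
#' muscles and each field (tendon, shortest fiber, longest fiber) in each
#' cheliceral state (closed, open), the raw length in microns and the
#' carapace-width size-corrected ratio, with extrapolation flags. Sides
#' `L`/`R` are averaged first; the carapace width of the matching
#' specimen/state divides each raw value.
#'
#' @param measurements Data frame with columns `muscle_name, state, side,
#'   tendon_um, shortest_fiber_um, longest_fiber_um` and either one
#'   `extrapolated` column (0/1, applied to all three fields) or per-field
#'   `tendon_extrapolated, shortest_fiber_extrapolated,
#'   longest_fiber_extrapolated`.
#' @param specimens Data frame with columns `state, carapace_width_um`
#'   (one row per scanned specimen/state; `specimen_id` optional).
#' @return Data frame, one row per muscle, with raw, `*_ratio` and
#'   `*_extrapolated` columns for each field x state, plus a `render`
#'   attribute-free companion via [format_morpho_table()].
#' @export
render_table <- function(measurements, specimens) {
  if (is.null(measurements) || !nrow(measurements)) {
    stop("empty measurement table")
  }
  fields <- c("tendon", "shortest_fiber", "longest_fiber")
  per_field <- paste0(fields, "_extrapolated")
  if (!all(per_field %in% names(measurements))) {
    if ("extrapolated" %in% names(measurements)) {
      for (f in per_field) measurements[[f]] <- measurements$extrapolated
    } else {
      for (f in per_field) measurements[[f]] <- 0
    }
  }
  need <- c("muscle_name", "state", "side",
            paste0(fields, "_um"), per_field)
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurements missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(c("state", "carapace_width_um") %in% names(specimens))) {
    stop("specimens table needs `state` and `carapace_width_um`")
  }

  as_meas <- function(row) {
    muscle_measurement(
      row$muscle_name, row$state, row$side, row$tendon_um,
      row$shortest_fiber_um, row$longest_fiber_um,
      extrapolated = as.logical(c(row$tendon_extrapolated,
                                  row$shortest_fiber_extrapolated,
                                  row$longest_fiber_extrapolated))
    )
  }
  states <- c("closed", "open")
  out <- data.frame(muscle_name = CHELICERAL_MUSCLES,
                    stringsAsFactors = FALSE)
  missing_rows <- character(0)
  for (st in states) {
    width <- specimens$carapace_width_um[specimens$state == st]
    if (length(width) != 1L || !is.finite(width) || width <= 0) {
      stop("need exactly one positive carapace width for state '", st, "'")
    }
    for (m in CHELICERAL_MUSCLES) {
      sub <- measurements[measurements$muscle_name == m &
                            measurements$state == st, , drop = FALSE]
      if (!nrow(sub)) {
        missing_rows <- c(missing_rows, paste(m, st, sep = " / "))
        next
      }
      meas <- if (nrow(sub) == 1L) {
        as_meas(sub[1, ])
      } else if (nrow(sub) == 2L && setequal(sub$side, c("L", "R"))) {
        average_sides(as_meas(sub[sub$side == "L", ]),
                      as_meas(sub[sub$side == "R", ]))
      } else {
        stop("expected one averaged row or an L/R pair for ",
             m, " / ", st, ", got ", nrow(sub), " rows")
      }
      i <- match(m, out$muscle_name)
      for (f in fields) {
        raw <- meas[[paste0(f, "_um")]]
        out[i, paste(f, st, "um", sep = "_")] <- raw
        out[i, paste(f, st, "ratio", sep = "_")] <- size_correct(raw, width)
        out[i, paste(f, st, "extrapolated", sep = "_")] <-
          unname(meas$extrapolated[f])
      }
    }
  }
  if (length(missing_rows)) {
    stop("missing muscle rows: ", paste(missing_rows, collapse = "; "))
  }
  class(out) <- c("morpho_table", "data.frame")
  out
}

#' Format the muscle table for display
#'
#' Renders each cell as `"raw (ratio)"` with the ratio rounded half-even
#' to two decimals and an asterisk marking extrapolated values, matching
#' the conventional presentation of such tables.
#'
#' @param table A [render_table()] result.
#' @return Character data frame: one row per muscle, one column per
#'   field x state.
#' @export
format_morpho_table <- function(table) {
  stopifnot(inherits(table, "morpho_table"))
  fields <- c("tendon", "shortest_fiber", "longest_fiber")
  states <- c("closed", "open")
  out <- data.frame(muscle_name = table$muscle_name, stringsAsFactors = FALSE)
  for (f in fields) {
    for (st in states) {
      raw <- table[[paste(f, st, "um", sep = "_")]]
      ratio <- round(table[[paste(f, st, "ratio", sep = "_")]], 2)
      star <- ifelse(table[[paste(f, st, "extrapolated", sep = "_")]], "*", "")
      out[[paste(f, st, sep = "_")]] <- sprintf(
        "%.2f%s (%.2f%s)", raw, star, ratio, star
      )
    }
  }
  out
}

#' Bundled micro-CT measurement fixture for *Pararchaea alba*
#'
#' Loads the published cheliceral muscle measurements (left/right already
#' averaged, microns) for the closed- and open-chelicerae scans, the two
#' specimens' carapace widths (500.4 and 495.5 microns), and the published
#' size-corrected ratios for cross-checking.
#'
#' @return List with data frames `measurements`, `specimens`,
#'   `printed_ratios`.
#' @export
pararchaea_table1 <- function() {
  f <- function(name) {
    utils::read.csv(
      system.file("extdata", name, package = "strikekin", mustWork = TRUE),
      stringsAsFactors = FALSE
    )
  }
  list(
    measurements = f("pararchaea_table1_muscles.csv"),
    specimens = f("pararchaea_specimens.csv"),
    printed_ratios = f("pararchaea_table1_printed_ratios.csv")
  )
}
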