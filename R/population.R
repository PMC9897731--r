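#' Pool cells from several animals into a common map
#'
#' Expresses each cell's coordinates relative to its animal's GRIN-lens
#' center and concatenates across animals. This translation-only alignment
#' is sufficient for the quantitative outputs downstream (overlap counts,
#' responder fractions), which do not depend on atlas warping.
#'
#' @param coords_by_animal named list of neurons x 2 matrices (um).
#' @param lens_centers named list (same names) of length-2 centers (um).
#' @return `CellMap` data.frame: `animal`, `neuron`, `x_um`, `y_um`.
#' @export
build_cell_map <- function(coords_by_animal, lens_centers) {
  if (is.null(names(coords_by_animal)) || any(names(coords_by_animal) == "")) {
    stop_invalid("coords_by_animal must be a named list")
  }
  missing <- setdiff(names(coords_by_animal), names(lens_centers))
  if (length(missing)) {
    stop_invalid("missing lens center for animal(s): ",
                 paste(missing, collapse = ", "))
  }
  rows <- lapply(names(coords_by_animal), function(a) {
    xy <- coords_by_animal[[a]]
    ctr <- lens_centers[[a]]
    if (length(ctr) != 2L || any(!is.finite(ctr))) {
      stop_invalid("lens center for ", a, " must be two finite numbers")
    }
    data.frame(animal = a, neuron = seq_len(nrow(xy)),
               x_um = xy[, 1] - ctr[1], y_um = xy[, 2] - ctr[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("CellMap", "data.frame")
  out
}

#' Venn-region counts of tone, movement-ON and footshock responders
#'
#' Counts the seven non-empty intersections of the three responder sets plus
#' the cells responding to none, for one day. Movement-ON responders are the
#' union of the CS and no-CS movement analyses by default.
#'
#' @param responder_table a `ResponderTable` (see [classify_responders()]).
#' @param day day label to summarize.
#' @param movon_kinds which movement-ON analyses define the movement set.
#' @return `OverlapSummary` list: named counts `tone`, `mov`, `shock`,
#'   `tone_mov`, `tone_shock`, `mov_shock`, `tone_mov_shock` (exclusive
#'   regions), `none`, and `total`.
#' @export
overlap_counts <- function(responder_table, day,
                           movon_kinds = c("movON_CS", "movON_noCS")) {
  tab <- responder_table[responder_table$day == day, , drop = FALSE]
  if (nrow(tab) == 0L) stop_invalid("responder table has no rows for day ", day)
  if (!"US" %in% tab$kind) {
    stop_invalid("footshock overlaps are only defined for sessions with USs")
  }
  neurons <- sort(unique(tab$neuron))
  in_set <- function(kinds) {
    neurons %in% tab$neuron[tab$kind %in% kinds & tab$responder]
  }
  tone <- in_set("CS_beep")
  mov <- in_set(movon_kinds)
  shock <- in_set("US")
  counts <- c(
    tone = sum(tone & !mov & !shock),
    mov = sum(!tone & mov & !shock),
    shock = sum(!tone & !mov & shock),
    tone_mov = sum(tone & mov & !shock),
    tone_shock = sum(tone & !mov & shock),
    mov_shock = sum(!tone & mov & shock),
    tone_mov_shock = sum(tone & mov & shock),
    none = sum(!tone & !mov & !shock)
  )
  structure(list(counts = counts, total = length(neurons), day = day),
            class = "OverlapSummary")
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf("<OverlapSummary> day=%s total=%d\n", x$day, x$total))
  print(x$counts)
  invisible(x)
}

#' Responder counts and fractions per day and event kind
#'
#' The per-day counts feed the chi-square test of responder-fraction change
#' across the protocol.
#'
#' @param responder_table a `ResponderTable`.
#' @return data.frame: `day`, `kind`, `n_responders`, `n_total`, `fraction`.
#' @export
fractions_by_day <- function(responder_table) {
  sp <- split(responder_table,
              list(responder_table$day, responder_table$kind), drop = TRUE)
  rows <- lapply(sp, function(g) {
    data.frame(day = g$day[1], kind = g$kind[1],
               n_responders = sum(g$responder), n_total = nrow(g),
               fraction = mean(g$responder))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$kind, out$day), , drop = FALSE]
}
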