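#' Generation time and rate-speedup parameters
#'
#' @param generation_time years per male generation (default 29).
#' @param speedup fractional rate increase `f` in `[0, 1)`; times rescale by
#'   `1 - f` under a faster clock (a pedigree-based rate ~14% faster than
#'   the ancient-DNA calibration gives `f = 0.14`).
#' @return an object of class `scenario_params`.
#' @export
scenario_params <- function(generation_time = 29, speedup = 0) {
  assert_scalar_num(generation_time, "generation_time",
                    lower = .Machine$double.xmin)
  assert_scalar_num(speedup, "speedup", 0, 1 - 1e-12)
  structure(list(generation_time = generation_time, speedup = speedup),
            class = "scenario_params")
}

#' Lineage table of the deep Y phylogeny
#'
#' A `lineage_table` holds named lineages with their origin (the split that
#' created them), the later split at which they diverge into named
#' children (`NA` while unbroken to the present), and a continental label
#' (`African`, `non-African`, or `both`). The default table carries the
#' point estimates for the deep splits: B/CT at 101,000 years ago, CT into
#' DE and CF at 77,000, C/FT at 76,000, D/E at 73,000, the D0/D split at
#' 71,000, divergence of E within Africa at 59,000, FT diversification at
#' 57,000, the D0 coalescence at 2,500, and the E-M35 origin/divergence at
#' 47,000/28,500. The unnamed stem between the D/E and D0/D splits is
#' carried as lineage `D0D`.
#'
#' @param df optional data.frame with columns `lineage`, `parent`, `origin`,
#'   `divergence`, `label` to validate instead of the default table.
#' @return a validated `lineage_table` data.frame.
#' @export
lineage_table <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      lineage    = c("B", "CT", "DE", "CF", "C", "FT", "E", "D0D", "D0", "D", "E-M35"),
      parent     = c(NA, NA, "CT", "CT", "CF", "CF", "DE", "DE", "D0D", "D0D", "E"),
      origin     = c(101000, 101000, 77000, 77000, 76000, 76000, 73000, 73000,
                     71000, 71000, 47000),
      divergence = c(NA, 77000, 73000, 76000, NA, 57000, 59000, 71000,
                     2500, NA, 28500),
      label      = c("African", "both", "both", "both", "non-African",
                     "non-African", "African", "both", "African",
                     "non-African", "both"),
      stringsAsFactors = FALSE)
  }
  need <- c("lineage", "parent", "origin", "divergence", "label")
  if (!all(need %in% names(df))) {
    stop("lineage table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$lineage)) stop("duplicate lineage names", call. = FALSE)
  if (!all(df$label %in% c("African", "non-African", "both"))) {
    stop("labels must be African, non-African or both", call. = FALSE)
  }
  bad <- !is.na(df$divergence) & df$origin <= df$divergence
  if (any(bad)) stop("origin must predate divergence for: ",
                     paste(df$lineage[bad], collapse = ", "), call. = FALSE)
  po <- df$origin[match(df$parent, df$lineage)]
  bad <- !is.na(po) & po < df$origin
  if (any(bad)) stop("child older than parent: ",
                     paste(df$lineage[bad], collapse = ", "), call. = FALSE)
  class(df) <- c("lineage_table", "data.frame")
  df
}

#' Read a lineage table from TSV
#' @param path TSV with the [lineage_table()] columns.
#' @return a validated `lineage_table`.
#' @export
read_lineage_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  lineage_table(df)
}

# lineages relevant to the out-of-Africa pattern: the root-most lineage with
# non-African descendants (label both/non-African) and everything below it.
relevant_lineages <- function(table) {
  non_afr <- table$lineage[table$label %in% c("both", "non-African")]
  anc <- non_afr[is.na(table$parent[match(non_afr, table$lineage)]) |
                   !(table$parent[match(non_afr, table$lineage)] %in% table$lineage)]
  if (length(anc) == 0L) anc <- non_afr[which.max(table$origin[match(non_afr, table$lineage)])]
  below <- anc
  repeat {
    kids <- table$lineage[table$parent %in% below & !(table$lineage %in% below)]
    if (length(kids) == 0L) break
    below <- c(below, kids)
  }
  below
}

#' Lineages extant at a time point
#'
#' A lineage is extant at time `t` (years ago) when it has already
#' originated (`origin >= t`) and has not yet diverged into its named
#' children (`t > divergence`, or no divergence recorded). With
#' `relevant_only = TRUE` (default) only lineages bearing on the
#' out-of-Africa pattern are returned: the root-most lineage with
#' non-African descendants and everything below it.
#'
#' @param table a [lineage_table()].
#' @param t time in years ago (> 0).
#' @param relevant_only restrict to out-of-Africa-relevant lineages.
#' @return character vector of lineage names (empty, with a warning, when
#'   `t` falls outside the table's span).
#' @export
extant_lineages <- function(table, t, relevant_only = TRUE) {
  table <- lineage_table(as.data.frame(table))
  assert_scalar_num(t, "t", lower = .Machine$double.xmin)
  if (t > max(table$origin)) {
    warning("t predates every lineage in the table", call. = FALSE)
    return(character())
  }
  ok <- table$origin >= t & (is.na(table$divergence) | t > table$divergence)
  out <- table$lineage[ok]
  if (relevant_only) out <- intersect(out, relevant_lineages(table))
  out
}

#' Enumerate out-of-Africa migration scenarios
#'
#' Builds the three exit windows implied by the lineage table: between the
#' B/CT split and the CT divergence a single out-of-Africa migration of CT
#' explains the present-day pattern but requires back-migration of the
#' African sublineages (D0 and E); between the C/FT and D/E splits three
#' lineages (C, DE, FT) migrate, again with D0/E back-migration; between
#' the D0/D split and the FT diversification five lineages are present and
#' migration of the exclusively non-African three (C, D, FT) requires no
#' back-migration. Every scenario additionally requires an E-M35 exit
#' between its origin and its divergence. Migrants are derived from the
#' extant relevant lineages with non-African descendants; back-migrations
#' from migrated `both`-labelled lineages' maximal African descendants.
#'
#' @param table a [lineage_table()]; must contain the required splits.
#' @param exclude_gaps drop the short between-scenario gaps (default); when
#'   `FALSE` the gaps are returned in an additional `gaps` element.
#' @return list of class `scenario_set` with elements `scenarios` (each with
#'   `id`, `exit = c(high, low)` years ago, `migrants`, `back_migrations`),
#'   `e_m35_exit`, and optionally `gaps`.
#' @export
scenario_windows <- function(table = lineage_table(), exclude_gaps = TRUE) {
  table <- lineage_table(as.data.frame(table))
  get <- function(lin, col) {
    v <- table[[col]][match(lin, table$lineage)]
    if (length(v) != 1L || is.na(v)) {
      stop(sprintf("lineage table is missing the %s of %s", col, lin),
           call. = FALSE)
    }
    v
  }
  windows <- list(
    c(high = get("CT", "origin"), low = get("CT", "divergence")),
    c(high = get("C", "origin"), low = get("DE", "divergence")),
    c(high = get("D0", "origin"), low = get("FT", "divergence")))
  label_of <- function(lin) table$label[match(lin, table$lineage)]
  african_descendants <- function(lin) {
    # maximal African-labelled descendants: stop descending once African
    out <- character(); frontier <- table$lineage[table$parent %in% lin]
    while (length(frontier) > 0L) {
      afr <- frontier[label_of(frontier) == "African"]
      out <- c(out, afr)
      frontier <- table$lineage[table$parent %in% setdiff(frontier, afr)]
    }
    sort(out)
  }
  scenarios <- lapply(seq_along(windows), function(k) {
    w <- windows[[k]]
    mid <- mean(w)
    ext <- extant_lineages(table, mid, relevant_only = TRUE)
    migrants <- ext[label_of(ext) %in% c("both", "non-African")]
    back <- list()
    for (m in migrants[label_of(migrants) == "both"]) {
      d <- african_descendants(m)
      if (length(d) > 0L) {
        back[[m]] <- list(
          lineages = d,
          interval = c(high = min(table$origin[match(d, table$lineage)]),
                       low = max(table$divergence[match(d, table$lineage)],
                                 na.rm = TRUE)))
      }
    }
    list(id = k, exit = w, migrants = sort(migrants), back_migrations = back)
  })
  out <- list(scenarios = scenarios,
              e_m35_exit = c(high = get("E-M35", "origin"),
                             low = get("E-M35", "divergence")))
  if (!exclude_gaps) {
    out$gaps <- list(
      c(high = unname(windows[[1]]["low"]), low = unname(windows[[2]]["high"])),
      c(high = unname(windows[[2]]["low"]), low = unname(windows[[3]]["high"])))
  }
  structure(out, class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  for (s in x$scenarios) {
    cat(sprintf("Scenario %d: exit %s-%s years ago; out: %s; back-migration: %s\n",
                s$id, format(s$exit["high"], big.mark = ","),
                format(s$exit["low"], big.mark = ","),
                paste(s$migrants, collapse = ", "),
                if (length(s$back_migrations) == 0) "none" else
                  paste(unlist(lapply(s$back_migrations, `[[`, "lineages")),
                        collapse = ", ")))
  }
  cat(sprintf("All scenarios: E-M35 exit %s-%s years ago\n",
              format(x$e_m35_exit["high"], big.mark = ","),
              format(x$e_m35_exit["low"], big.mark = ",")))
  invisible(x)
}

#' Rescale times under a faster mutation rate
#'
#' A rate faster by fraction `f` makes every time estimate more recent by
#' the same fraction: each value is multiplied by `1 - f` and rounded
#' half-up to `round_to` years (default 1,000, the convention for scenario
#' bounds; use `round_to = NULL` for raw values).
#'
#' @param values numeric vector of times in years.
#' @param f fractional rate speedup in `[0, 1)`.
#' @param round_to rounding unit in years, or `NULL`.
#' @return numeric vector of rescaled times.
#' @examples
#' rescale_times(c(101000, 77000), 0.14)  # 87000, 66000
#' @export
rescale_times <- function(values, f, round_to = 1000) {
  assert_scalar_num(f, "f", 0, 1 - 1e-12)
  out <- values * (1 - f)
  if (!is.null(round_to)) out <- round_half_up(out, round_to)
  out
}

#' Date an admixture event from fossil age and generations before it
#'
#' Adds a range of generations (converted to years with the generation
#' time) to a fossil's calibrated age range: the introgressed-segment
#' clock dates Neanderthal admixture to 232-430 generations before the
#' 43,210-46,880-year-old Siberian genome, i.e. 49,900-59,400 years ago at
#' 29 years per generation.
#'
#' @param fossil_age_low,fossil_age_high fossil age range in years.
#' @param gen_low,gen_high generations before the fossil lived.
#' @param params a [scenario_params()] (generation time).
#' @param round_to rounding unit (default nearest 100 years, half-up).
#' @return `c(low, high)` in years ago.
#' @export
admixture_window <- function(fossil_age_low, fossil_age_high, gen_low,
                             gen_high, params = scenario_params(),
                             round_to = 100) {
  stopifnot(fossil_age_low > 0, fossil_age_low <= fossil_age_high,
            gen_low >= 0, gen_low <= gen_high)
  low <- fossil_age_low + gen_low * params$generation_time
  high <- fossil_age_high + gen_high * params$generation_time
  out <- c(low = low, high = high)
  if (!is.null(round_to)) out <- round_half_up(out, round_to)
  out
}

#' Intersect two time windows
#'
#' Windows are intervals in years ago given as `c(high, low)` (or any
#' order; names `high`/`low` are assigned). Returns the overlap, or `NULL`
#' when the windows are disjoint.
#'
#' @param a,b numeric length-2 intervals in years ago.
#' @return `c(high, low)` overlap, or `NULL` (empty).
#' @export
intersect_windows <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NULL)
  ah <- max(a); al <- min(a); bh <- max(b); bl <- min(b)
  hi <- min(ah, bh); lo <- max(al, bl)
  if (lo > hi) return(NULL)
  c(high = hi, low = lo)
}
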