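#' @keywords internal
"_PACKAGE"

#' Total Oxford Knee Score
#'
#' Sums the 12 item responses. Items are coded 0 (severe) to 4 (very mild),
#' so the total ranges 0--48 with 48 the best knee health.
#'
#' @param items integer vector of length 12, or an n x 12 matrix/data frame of
#'   responses, each entry in 0..4.
#' @return integer total(s) in 0..48.
#' @examples
#' oks_total(rep(4, 12))  # 48
#' @export
oks_total <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 12L) stop("expected 12 OKS items", call. = FALSE)
    check_range(items, 0L, 4L, "OKS items")
    return(as.integer(rowSums(items)))
  }
  if (length(items) != 12L) stop("expected 12 OKS items", call. = FALSE)
  check_range(items, 0L, 4L, "OKS items")
  as.integer(sum(items))
}

#' Classify an OKS total into a severity band
#'
#' Bands partition 0--48 exactly: severe 0--19, moderate 20--29, mild 30--39,
#' very mild 40--48.
#'
#' @param score integer total(s) in 0..48.
#' @return factor with levels `severe`, `moderate`, `mild`, `very_mild`
#'   (worst to best).
#' @examples
#' oks_severity(45)  # very_mild
#' @export
oks_severity <- function(score) {
  check_range(score, 0L, 48L, "OKS total")
  cut(score, breaks = c(-1L, 19L, 29L, 39L, 48L),
      labels = c("severe", "moderate", "mild", "very_mild"))
}

#' EQ-5D-5L domain order used throughout the package
#'
#' Mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression -- the instrument's listing order, fixed everywhere.
#'
#' @return character vector of the five domain codes.
#' @export
eq_domains <- function() c("mo", "sc", "ua", "pd", "ad")

#' Enumerate all EQ-5D-5L profiles
#'
#' The descriptive system has five domains (mobility, self-care, usual
#' activities, pain/discomfort, anxiety/depression) at five levels each,
#' giving 5^5 = 3125 profiles coded as five-digit strings from `"11111"`
#' (full health) to `"55555"` (worst health).
#'
#' @return data.frame with columns `mo, sc, ua, pd, ad` (integer levels) and
#'   `code` (character), in lexicographic code order.
#' @export
eq_profiles <- function() {
  g <- expand.grid(ad = 1:5, pd = 1:5, ua = 1:5, sc = 1:5, mo = 1:5,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g))]
  g$code <- profile_code(g)
  g <- g[order(g$code), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Convert domain levels to profile codes and back
#'
#' @param levels an n x 5 matrix/data frame of levels in domain order
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression, each in 1..5.
#' @param code character vector of five-digit profile codes.
#' @return `profile_code` returns the five-digit codes; `profile_levels` the
#'   n x 5 integer matrix.
#' @examples
#' profile_code(matrix(c(1, 2, 3, 4, 5), 1))  # "12345"
#' @export
profile_code <- function(levels) {
  if (is.data.frame(levels)) levels <- as.matrix(levels[, seq_len(5)])
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  if (ncol(levels) != 5L) stop("expected 5 domain levels", call. = FALSE)
  check_range(levels, 1L, 5L, "EQ-5D levels")
  apply(levels, 1L, paste0, collapse = "")
}

#' @rdname profile_code
#' @export
profile_levels <- function(code) {
  if (any(nchar(code) != 5L) || any(grepl("[^1-5]", code))) {
    stop("profile codes must be five digits, each 1-5", call. = FALSE)
  }
  m <- t(vapply(strsplit(code, ""), function(s) as.integer(s), integer(5)))
  colnames(m) <- eq_domains()
  m
}

#' Read a country value set (tariff)
#'
#' Two dialects are supported. `additive`: delimited text with columns
#' `domain, level, decrement` (domains `mo, sc, ua, pd, ad`; levels 2..5)
#' plus one row with `domain = "constant"` holding the full-health value;
#' utilities are the constant minus the decrements of each domain level above
#' 1. `lookup`: columns `profile_code, utility` covering all 3125 profiles
#' exactly once. Crosswalk tariffs, and any tariff with interaction terms,
#' are supplied in lookup form.
#'
#' @param path CSV file path.
#' @param dialect `"additive"` or `"lookup"`.
#' @param country label attached to the value set.
#' @param tariff_type `"VT"` (valuation) or `"CW"` (crosswalk).
#' @return an object of class `eq_value_set`.
#' @export
read_value_set <- function(path, dialect = c("additive", "lookup"),
                           country = basename(path), tariff_type = "VT") {
  dialect <- match.arg(dialect)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "additive") {
    need <- c("domain", "level", "decrement")
    if (!all(need %in% names(tab))) {
      stop("additive value set needs columns domain, level, decrement",
           call. = FALSE)
    }
    dec <- suppressWarnings(as.numeric(tab$decrement))
    if (any(is.na(dec))) stop("non-numeric decrement values", call. = FALSE)
    const_row <- tab$domain == "constant"
    if (sum(const_row) != 1L) {
      stop("additive value set needs exactly one 'constant' row", call. = FALSE)
    }
    constant <- dec[const_row]
    coef <- matrix(0, nrow = 5L, ncol = 4L,
                   dimnames = list(eq_domains(), paste0("L", 2:5)))
    body <- tab[!const_row, , drop = FALSE]
    lev <- as.integer(body$level)
    if (any(!body$domain %in% eq_domains()) || any(is.na(lev)) ||
        any(lev < 2L | lev > 5L)) {
      stop("additive rows must have domain in mo/sc/ua/pd/ad and level 2-5",
           call. = FALSE)
    }
    key <- paste(body$domain, lev)
    if (anyDuplicated(key)) stop("duplicate domain/level rows", call. = FALSE)
    miss <- setdiff(as.vector(outer(eq_domains(), 2:5, paste)), key)
    if (length(miss)) {
      stop("missing decrement rows: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    coef[cbind(match(body$domain, eq_domains()), lev - 1L)] <-
      dec[!const_row]
    vs <- list(country = country, tariff_type = tariff_type,
               dialect = "additive", constant = constant, coef = coef)
  } else {
    need <- c("profile_code", "utility")
    if (!all(need %in% names(tab))) {
      stop("lookup value set needs columns profile_code, utility",
           call. = FALSE)
    }
    u <- suppressWarnings(as.numeric(tab$utility))
    if (any(is.na(u))) stop("non-numeric utility values", call. = FALSE)
    codes <- tab$profile_code
    if (anyDuplicated(codes)) {
      stop("duplicate profile rows: ",
           paste(utils::head(codes[duplicated(codes)], 5), collapse = ", "),
           call. = FALSE)
    }
    all_codes <- eq_profiles()$code
    miss <- setdiff(all_codes, codes)
    if (length(miss)) {
      stop("lookup table incomplete; first missing code: ", miss[[1L]],
           call. = FALSE)
    }
    table <- u[match(all_codes, codes)]
    names(table) <- all_codes
    vs <- list(country = country, tariff_type = tariff_type,
               dialect = "lookup", table = table)
  }
  structure(vs, class = "eq_value_set")
}

#' Materialize an additive value set as a full lookup table
#'
#' @param vs an `eq_value_set`.
#' @return an `eq_value_set` of dialect `lookup` with identical utilities.
#' @export
as_lookup <- function(vs) {
  stopifnot(inherits(vs, "eq_value_set"))
  if (vs$dialect == "lookup") return(vs)
  prof <- eq_profiles()
  u <- eq_utility(prof, vs)
  names(u) <- prof$code
  structure(list(country = vs$country, tariff_type = vs$tariff_type,
                 dialect = "lookup", table = u), class = "eq_value_set")
}

#' Convert EQ-5D-5L profiles to utilities
#'
#' @param profiles five-digit code vector, an n x 5 level matrix, or the data
#'   frame returned by [eq_profiles()].
#' @param vs an `eq_value_set`.
#' @return numeric utilities (1 = full health; states worse than dead are
#'   negative under tariffs that allow them).
#' @examples
#' vs <- toy_value_set()
#' eq_utility("11111", vs)  # 1
#' @export
eq_utility <- function(profiles, vs) {
  stopifnot(inherits(vs, "eq_value_set"))
  if (is.character(profiles)) {
    lv <- profile_levels(profiles)
    codes <- profiles
  } else {
    lv <- profile_levels(profile_code(profiles))
    codes <- profile_code(profiles)
  }
  if (vs$dialect == "additive") {
    dec <- vapply(seq_len(5), function(d) {
      l <- lv[, d]
      ifelse(l > 1L, vs$coef[d, ][l - 1L], 0)
    }, numeric(nrow(lv)))
    if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1L)
    vs$constant - rowSums(dec)
  } else {
    out <- vs$table[codes]
    if (any(is.na(out))) {
      stop("profile missing from lookup table: ",
           codes[which(is.na(out))[1L]], call. = FALSE)
    }
    unname(out)
  }
}

#' @export
print.eq_value_set <- function(x, ...) {
  cat(sprintf("EQ-5D-5L value set '%s' (%s, %s dialect)\n",
              x$country, x$tariff_type, x$dialect))
  invisible(x)
}

#' Bundled toy value sets
#'
#' Two synthetic tariffs ship with the package for testing and worked
#' examples: an additive one (main-effects decrements, full health 1, worst
#' state -0.20) and a lookup one derived from different decrements plus a
#' small extra penalty whenever any domain is at level 4 or 5, so that it is
#' genuinely non-additive. Real country tariffs are not bundled; they load
#' through [read_value_set()].
#'
#' @param which `"additive"` or `"lookup"`.
#' @return an `eq_value_set`.
#' @export
toy_value_set <- function(which = c("additive", "lookup")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      if (which == "additive") "valueset_toy_additive.csv"
                      else "valueset_toy_lookup.csv",
                      package = "oksmap")
  read_value_set(path, dialect = which,
                 country = paste0("toy_", which), tariff_type = "VT")
}
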