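#' Gaussian membership function
#'
#' `mu(x) = exp(-(x - center)^2 / (2 sigma^2))`, the membership-function
#' shape used for every linguistic term in the fatigue classifier.
#'
#' @param label linguistic term name (e.g. `"low"`).
#' @param center peak position, in normalized feature units.
#' @param sigma width, `> 0`.
#' @return An object of class `gaussian_mf`.
#' @export
gaussian_mf <- function(label, center, sigma) {
  if (!is.finite(center) || !is.finite(sigma) || sigma <= 0) {
    stop("gaussian_mf: center must be finite and sigma > 0", call. = FALSE)
  }
  structure(list(label = as.character(label), center = center, sigma = sigma),
            class = "gaussian_mf")
}

#' Membership degrees of a crisp value in a set of Gaussian terms
#'
#' @param value a finite crisp input (normalized feature units).
#' @param mfs list of [gaussian_mf()] terms.
#' @return Named numeric vector of memberships in `(0, 1]`, one per term.
#' @examples
#' fuzzify(0.9, list(gaussian_mf("high", 1, 0.1), gaussian_mf("low", 0.6, 0.1)))
#' @export
fuzzify <- function(value, mfs) {
  if (!is.finite(value)) stop("fuzzify: value must be finite", call. = FALSE)
  out <- vapply(mfs, function(mf) {
    exp(-(value - mf$center)^2 / (2 * mf$sigma^2))
  }, numeric(1))
  names(out) <- vapply(mfs, `[[`, character(1), "label")
  out
}

#' Mamdani fuzzy rule base for fatigue estimation
#'
#' @param input_vars named list of input variables. Each entry is a list
#'   with `terms` (list of [gaussian_mf()]) and `range` (length-2 numeric;
#'   crisp inputs are clamped into this range before fuzzification, so the
#'   Gaussian terms saturate rather than decay outside their calibrated
#'   span).
#' @param output_var list with `name`, `terms` and `range` for the crisp
#'   output (fatigue level on `[0, 1]` by default).
#' @param rules list of rules; each rule is a list with `antecedent`
#'   (named character vector/list mapping input-variable names to term
#'   labels, combined with AND) and `consequent` (an output term label).
#' @return A validated object of class `fuzzy_rule_base`.
#' @seealso [default_rule_base()], [infer_fatigue()]
#' @export
fuzzy_rule_base <- function(input_vars, output_var, rules) {
  rb <- structure(list(input_vars = input_vars, output_var = output_var,
                       rules = rules),
                  class = "fuzzy_rule_base")
  validate_rule_base(rb)
  rb
}

#' Validate a fuzzy rule base
#'
#' Checks that at least one rule exists, that every rule references
#' defined variables and terms, that all widths are positive and that the
#' output terms cover the output range (aggregate membership nowhere
#' negligible).
#'
#' @param rb a `fuzzy_rule_base`.
#' @return `rb`, invisibly; errors on violation.
#' @export
validate_rule_base <- function(rb) {
  stopifnot(inherits(rb, "fuzzy_rule_base"))
  if (length(rb$rules) < 1) {
    stop("fuzzy_rule_base: at least one rule required", call. = FALSE)
  }
  term_labels <- function(v) vapply(v$terms, `[[`, character(1), "label")
  for (vn in names(rb$input_vars)) {
    v <- rb$input_vars[[vn]]
    if (length(v$range) != 2 || v$range[1] >= v$range[2]) {
      stop(sprintf("fuzzy_rule_base: bad range for input '%s'", vn),
           call. = FALSE)
    }
  }
  out_labels <- term_labels(rb$output_var)
  for (i in seq_along(rb$rules)) {
    r <- rb$rules[[i]]
    ant <- r$antecedent
    if (length(ant) < 1) {
      stop(sprintf("fuzzy_rule_base: rule %d has empty antecedent", i),
           call. = FALSE)
    }
    for (vn in names(ant)) {
      if (!vn %in% names(rb$input_vars)) {
        stop(sprintf("fuzzy_rule_base: rule %d references unknown input '%s'",
                     i, vn), call. = FALSE)
      }
      if (!ant[[vn]] %in% term_labels(rb$input_vars[[vn]])) {
        stop(sprintf("fuzzy_rule_base: rule %d references unknown term '%s' of '%s'",
                     i, ant[[vn]], vn), call. = FALSE)
      }
    }
    if (!r$consequent %in% out_labels) {
      stop(sprintf("fuzzy_rule_base: rule %d has unknown consequent '%s'",
                   i, r$consequent), call. = FALSE)
    }
  }
  grid <- seq(rb$output_var$range[1], rb$output_var$range[2],
              length.out = 201)
  cover <- Reduce(pmax, lapply(rb$output_var$terms, function(mf) {
    exp(-(grid - mf$center)^2 / (2 * mf$sigma^2))
  }))
  if (min(cover) < 1e-3) {
    stop("fuzzy_rule_base: output terms do not cover the output range",
         call. = FALSE)
  }
  invisible(rb)
}

#' @export
print.fuzzy_rule_base <- function(x, ...) {
  cat(sprintf("fuzzy_rule_base: %d inputs (%s), %d rules, output '%s' on [%g, %g]\n",
              length(x$input_vars), paste(names(x$input_vars), collapse = ", "),
              length(x$rules), x$output_var$name,
              x$output_var$range[1], x$output_var$range[2]))
  invisible(x)
}

#' Mamdani inference: normalized EMG features to a fatigue level
#'
#' Classic min/max Mamdani pipeline: crisp inputs are clamped to each
#' variable's range and fuzzified through its Gaussian terms; rule
#' activation is the minimum antecedent membership (AND); each rule clips
#' its consequent term at its activation; clipped terms are aggregated by
#' maximum; the crisp output is the Centre of Area (CoA) centroid of the
#' aggregate over a uniform discretization of the output range.
#'
#' If no rule fires above `1e-6` the inference is degenerate and the
#' mid-range level (0.5 on the default `[0, 1]` scale) is returned with a
#' warning and `degenerate = TRUE`, so a running session never aborts on a
#' pathological window.
#'
#' @param features named numeric vector or list of normalized feature
#'   values; names must include every input variable a rule uses
#'   (`MNF`, `MNP`, `FR`, `PSR` for the default base).
#' @param rb a [fuzzy_rule_base()]; default [default_rule_base()].
#' @param grid_n number of CoA discretization points; default 1001.
#' @return An object of class `fatigue_estimate`: list with `level` in the
#'   output range, `fired_rules` (data frame of rule index, consequent and
#'   activation) and logical `degenerate`.
#' @export
infer_fatigue <- function(features, rb = default_rule_base(),
                          grid_n = 1001) {
  validate_rule_base(rb)
  features <- as.list(features)
  # memberships per input variable, inputs clamped to the variable range
  memb <- list()
  for (vn in names(rb$input_vars)) {
    if (is.null(features[[vn]])) next
    v <- rb$input_vars[[vn]]
    x <- min(max(features[[vn]], v$range[1]), v$range[2])
    memb[[vn]] <- fuzzify(x, v$terms)
  }
  act <- vapply(rb$rules, function(r) {
    vals <- vapply(names(r$antecedent), function(vn) {
      if (is.null(memb[[vn]])) {
        stop(sprintf("infer_fatigue: feature '%s' required by a rule is missing",
                     vn), call. = FALSE)
      }
      memb[[vn]][[r$antecedent[[vn]]]]
    }, numeric(1))
    min(vals)
  }, numeric(1))
  fired <- data.frame(
    rule = seq_along(rb$rules),
    consequent = vapply(rb$rules, `[[`, character(1), "consequent"),
    activation = act
  )
  rng <- rb$output_var$range
  if (max(act) < 1e-6) {
    warning("infer_fatigue: no rule fired; returning mid-range level",
            call. = FALSE)
    return(structure(list(level = mean(rng), fired_rules = fired,
                          degenerate = TRUE),
                     class = "fatigue_estimate"))
  }
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  agg <- numeric(grid_n)
  out_terms <- rb$output_var$terms
  labels <- vapply(out_terms, `[[`, character(1), "label")
  for (i in seq_along(rb$rules)) {
    mf <- out_terms[[match(fired$consequent[i], labels)]]
    clipped <- pmin(act[i], exp(-(grid - mf$center)^2 / (2 * mf$sigma^2)))
    agg <- pmax(agg, clipped)
  }
  structure(list(level = sum(grid * agg) / sum(agg),
                 fired_rules = fired, degenerate = FALSE),
            class = "fatigue_estimate")
}

#' @export
print.fatigue_estimate <- function(x, ...) {
  cat(sprintf("fatigue_estimate: level %.3f%s\n", x$level,
              if (x$degenerate) " (degenerate: no rule fired)" else ""))
  top <- x$fired_rules[order(-x$fired_rules$activation), ][1:min(3, nrow(x$fired_rules)), ]
  cat("  strongest rules:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    rule %d -> %s (%.3f)\n",
                top$rule[i], top$consequent[i], top$activation[i]))
  }
  invisible(x)
}

# Single-antecedent rule helper.
.rule <- function(var, term, consequent) {
  list(antecedent = stats::setNames(list(term), var), consequent = consequent)
}

#' Default fatigue rule base
#'
#' Ships a three-term (low/medium/high) Gaussian partition per input and
#' output, with rules encoding the physiological monotone pattern of
#' developing fatigue: mean frequency and power-spectrum ratio fall while
#' mean power and frequency ratio rise. Inputs are expected as
#' baseline-normalized features (value divided by its fresh-muscle
#' baseline, see [normalize_features()]), so fresh muscle sits near 1 on
#' every axis. Term centers and widths are package defaults, editable via
#' the YAML serialization ([write_rule_base()]); they are a documented
#' working configuration, not a claim about any particular clinical
#' calibration.
#'
#' @return A [fuzzy_rule_base()].
#' @export
default_rule_base <- function() {
  g <- gaussian_mf
  fuzzy_rule_base(
    input_vars = list(
      MNF = list(range = c(0.6, 1.0),
                 terms = list(g("high", 1.0, 0.08), g("medium", 0.8, 0.08),
                              g("low", 0.6, 0.08))),
      MNP = list(range = c(1.0, 2.2),
                 terms = list(g("low", 1.0, 0.24), g("medium", 1.6, 0.24),
                              g("high", 2.2, 0.24))),
      FR = list(range = c(1.0, 1.6),
                terms = list(g("low", 1.0, 0.12), g("medium", 1.3, 0.12),
                             g("high", 1.6, 0.12))),
      PSR = list(range = c(0.7, 1.0),
                 terms = list(g("high", 1.0, 0.06), g("medium", 0.85, 0.06),
                              g("low", 0.7, 0.06)))
    ),
    output_var = list(
      name = "fatigue", range = c(0, 1),
      terms = list(g("low", 0.05, 0.12), g("medium", 0.5, 0.12),
                   g("high", 0.95, 0.12))
    ),
    rules = list(
      .rule("MNF", "high", "low"),
      .rule("MNF", "medium", "medium"),
      .rule("MNF", "low", "high"),
      .rule("MNP", "low", "low"),
      .rule("MNP", "medium", "medium"),
      .rule("MNP", "high", "high"),
      .rule("FR", "low", "low"),
      .rule("FR", "medium", "medium"),
      .rule("FR", "high", "high"),
      .rule("PSR", "high", "low"),
      .rule("PSR", "medium", "medium"),
      .rule("PSR", "low", "high")
    )
  )
}

#' Normalize a windowed feature table against its session baseline
#'
#' Divides each feature column by its mean over the first
#' `baseline_windows` rows, making the classifier subject-relative: fresh
#' muscle maps to roughly 1 on every axis regardless of electrode gain or
#' subject.
#'
#' @param feats data frame from [windowed_features()].
#' @param baseline_windows number of initial windows defining the fresh
#'   baseline; default 5.
#' @return Data frame with columns `window_start_s`, `MNF`, `MNP`, `FR`,
#'   `PSR` (normalized).
#' @export
normalize_features <- function(feats, baseline_windows = 5) {
  cols <- c("mnf_hz", "mnp", "fr", "psr")
  if (!all(cols %in% names(feats))) {
    stop("normalize_features: expected windowed_features() columns",
         call. = FALSE)
  }
  k <- min(baseline_windows, nrow(feats))
  base <- vapply(cols, function(cl) mean(feats[[cl]][1:k]), numeric(1))
  if (any(base <= 0)) {
    stop("normalize_features: non-positive baseline feature", call. = FALSE)
  }
  data.frame(window_start_s = feats$window_start_s,
             MNF = feats$mnf_hz / base[["mnf_hz"]],
             MNP = feats$mnp / base[["mnp"]],
             FR = feats$fr / base[["fr"]],
             PSR = feats$psr / base[["psr"]])
}

#' Fatigue level time course from a windowed feature table
#'
#' Normalizes the features against the session baseline and runs the fuzzy
#' classifier on every window.
#'
#' @inheritParams normalize_features
#' @param rb a [fuzzy_rule_base()].
#' @return Data frame with columns `window_start_s` and `fatigue`.
#' @export
estimate_fatigue_trace <- function(feats, rb = default_rule_base(),
                                   baseline_windows = 5) {
  nf <- normalize_features(feats, baseline_windows)
  lev <- vapply(seq_len(nrow(nf)), function(i) {
    infer_fatigue(as.list(nf[i, c("MNF", "MNP", "FR", "PSR")]), rb)$level
  }, numeric(1))
  data.frame(window_start_s = nf$window_start_s, fatigue = lev)
}

#' Write a rule base to YAML
#'
#' @param rb a [fuzzy_rule_base()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rule_base <- function(rb, path) {
  validate_rule_base(rb)
  ser_terms <- function(terms) {
    lapply(terms, function(mf) {
      list(label = mf$label, center = mf$center, sigma = mf$sigma)
    })
  }
  doc <- list(
    variables = lapply(rb$input_vars, function(v) {
      list(range = as.numeric(v$range), terms = ser_terms(v$terms))
    }),
    output = list(name = rb$output_var$name,
                  range = as.numeric(rb$output_var$range),
                  terms = ser_terms(rb$output_var$terms)),
    rules = lapply(rb$rules, function(r) {
      list(`if` = as.list(r$antecedent), then = r$consequent)
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a rule base from YAML
#'
#' @param path file written by [write_rule_base()] (or hand-edited to the
#'   same schema).
#' @return A validated [fuzzy_rule_base()].
#' @export
read_rule_base <- function(path) {
  doc <- yaml::read_yaml(path)
  de_terms <- function(terms) {
    lapply(terms, function(t) gaussian_mf(t$label, t$center, t$sigma))
  }
  fuzzy_rule_base(
    input_vars = lapply(doc$variables, function(v) {
      list(range = as.numeric(v$range), terms = de_terms(v$terms))
    }),
    output_var = list(name = doc$output$name,
                      range = as.numeric(doc$output$range),
                      terms = de_terms(doc$output$terms)),
    rules = lapply(doc$rules, function(r) {
      list(antecedent = r$`if`, consequent = r$then)
    })
  )
}
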