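#' Vertebral levels entering the Spinal Deformity Index
#'
#' The thirteen vertebrae T4 through L4 whose semiquantitative grades are
#' summed into the SDI.
#'
#' @format Character vector of length 13.
#' @export
SDI_VERTEBRAE <- c(paste0("T", 4:12), paste0("L", 1:4))

#' Vertebral heights from six-point morphometry landmarks
#'
#' Standard six-point morphometry places a superior and an inferior landmark
#' at the anterior, middle and posterior borders of the vertebral body; each
#' height is the Euclidean distance between the corresponding pair, so the
#' result is invariant to rigid rotation and translation of the radiograph.
#'
#' @param points Numeric 6 x 2 matrix (columns x, y in mm), rows ordered
#'   anterior-superior, anterior-inferior, middle-superior, middle-inferior,
#'   posterior-superior, posterior-inferior.
#' @return Named numeric vector `c(h_a, h_m, h_p)` in mm.
#' @export
heights_from_landmarks <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || !all(dim(points) == c(6L, 2L))) {
    stop("`points` must be a numeric 6 x 2 matrix of landmark coordinates",
         call. = FALSE)
  }
  pair <- function(i) sqrt(sum((points[i, ] - points[i + 1L, ])^2))
  h <- c(h_a = pair(1L), h_m = pair(3L), h_p = pair(5L))
  if (any(h <= .Machine$double.eps^0.5)) {
    stop("degenerate geometry: coincident superior/inferior landmarks ",
         "(zero height)", call. = FALSE)
  }
  h
}

#' Semiquantitative (Genant) grade of a vertebra
#'
#' Grades vertebral deformity from height compression. The compression is the
#' largest relative height loss among anterior wedge (1 - h_a/h_p), biconcave
#' (1 - h_m/h_p) and crush (1 - h_p/h_p_reference) patterns. Bands: grade 0
#' below 20\%, grade 1 (mild) 20-25\%, grade 2 (moderate) 25-40\%, grade 3
#' (severe) above 40\%. Boundary convention (the mild and moderate bands share
#' the printed 25\% edge): exactly 20\% is grade 1, exactly 25\% and exactly
#' 40\% are grade 2.
#'
#' @param h_a,h_m,h_p Anterior, middle, posterior heights (mm), positive.
#' @param h_p_reference Posterior height of an adjacent intact vertebra used
#'   for crush deformity; defaults to `h_p` (no crush information).
#' @return Integer grade in 0:3 (vectorised over the inputs).
#' @export
sq_grade <- function(h_a, h_m, h_p, h_p_reference = h_p) {
  n <- max(length(h_a), length(h_m), length(h_p), length(h_p_reference))
  h_a <- rep_len(h_a, n); h_m <- rep_len(h_m, n)
  h_p <- rep_len(h_p, n); h_p_reference <- rep_len(h_p_reference, n)
  if (any(!is.finite(c(h_a, h_m, h_p, h_p_reference))) ||
      any(c(h_a, h_m, h_p, h_p_reference) <= 0)) {
    stop("vertebral heights must be positive and finite", call. = FALSE)
  }
  comp <- pmax(1 - h_a / h_p, 1 - h_m / h_p, 1 - h_p / h_p_reference)
  grade_from_compression(comp)
}

grade_from_compression <- function(comp) {
  comp <- round(comp, 9)  # keep exact band edges stable under 1 - a/b rounding
  ifelse(comp < 0.20, 0L, ifelse(comp < 0.25, 1L, ifelse(comp <= 0.40, 2L, 3L)))
}

#' Grade all thirteen vertebrae of one patient
#'
#' Applies [sq_grade()] at each level T4-L4. The crush reference for each
#' vertebra is the mean posterior height of its two neighbours when both are
#' available, the single neighbour at the T4 and L4 ends.
#'
#' @param morpho Data frame with columns `vertebra` (all of [SDI_VERTEBRAE]),
#'   `h_a`, `h_m`, `h_p`.
#' @return Named integer vector of 13 grades, in T4..L4 order.
#' @export
grade_vertebrae <- function(morpho) {
  stopifnot(is.data.frame(morpho),
            all(c("vertebra", "h_a", "h_m", "h_p") %in% names(morpho)))
  if (!setequal(morpho$vertebra, SDI_VERTEBRAE) ||
      nrow(morpho) != length(SDI_VERTEBRAE)) {
    stop("morphometry must contain each of the 13 vertebrae T4-L4 exactly once",
         call. = FALSE)
  }
  m <- morpho[match(SDI_VERTEBRAE, morpho$vertebra), ]
  k <- nrow(m)
  ref <- vapply(seq_len(k), function(i) {
    nb <- c(if (i > 1L) m$h_p[i - 1L], if (i < k) m$h_p[i + 1L])
    if (length(nb) == 0L) m$h_p[i] else mean(nb)
  }, numeric(1))
  g <- sq_grade(m$h_a, m$h_m, m$h_p, ref)
  stats::setNames(g, SDI_VERTEBRAE)
}

#' Spinal Deformity Index and study endpoints
#'
#' The SDI sums the semiquantitative grades of the 13 vertebrae T4-L4
#' (range 0-39), integrating fracture number and severity. Two case/control
#' endpoints are derived: `sdi1` (case when SDI >= 1, control when SDI = 0)
#' and `sdi5` (case when SDI >= 5, control when SDI = 0, excluded for SDI
#' 1-4).
#'
#' @param grades Integer vector of 13 grades in 0:3.
#' @return List of class `sdi_score` with elements `sdi`, `endpoint1`
#'   (`"case"`/`"control"`), `endpoint2` (`"case"`/`"control"`/`"excluded"`).
#' @export
sdi_score <- function(grades) {
  grades <- as.integer(grades)
  if (length(grades) != 13L || anyNA(grades) || any(!grades %in% 0:3)) {
    stop("`grades` must be 13 semiquantitative grades in {0,1,2,3}",
         call. = FALSE)
  }
  s <- sum(grades)
  structure(list(
    sdi = s,
    endpoint1 = if (s >= 1L) "case" else "control",
    endpoint2 = if (s >= 5L) "case" else if (s == 0L) "control" else "excluded"
  ), class = "sdi_score")
}

#' Endpoint labels for a vector of SDI values
#'
#' @param sdi Integer vector of SDI values.
#' @param endpoint `"sdi1"` or `"sdi5"`.
#' @return Character vector `"case"`/`"control"`/`"excluded"` (the latter only
#'   for `sdi5`, SDI 1-4).
#' @export
sdi_endpoint <- function(sdi, endpoint = c("sdi1", "sdi5")) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.numeric(sdi), all(sdi >= 0))
  if (endpoint == "sdi1") {
    ifelse(sdi >= 1, "case", "control")
  } else {
    ifelse(sdi >= 5, "case", ifelse(sdi == 0, "control", "excluded"))
  }
}

#' Cohen's kappa for inter-reader agreement
#'
#' Chance-corrected agreement between two raters of the same items:
#' kappa = (p_o - p_e) / (1 - p_e), with p_o the observed agreement and p_e
#' the agreement expected from the raters' marginal frequencies.
#'
#' @param ratings_a,ratings_b Equal-length vectors of categorical ratings.
#' @return Numeric kappa. When both raters are constant and identical the
#'   statistic is undefined (p_e = 1); returns 1 with a warning.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) == 0L) {
    stop("ratings must be non-empty vectors of equal length", call. = FALSE)
  }
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - p_e < .Machine$double.eps) {
    warning("both raters constant and identical: kappa undefined, ",
            "returning 1 (perfect agreement)")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}
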