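# Orthogonal discrete wavelet transform, built from scratch on the periodic
# filter-bank cascade.  Signals are first symmetrically padded to the next
# power of two, transformed with an orthogonal matrix operator (inverse =
# transpose), and cropped after reconstruction.  Filter coefficients below
# are the standard published Daubechies / Symlet / Coiflet scaling filters.

WAVELET_DEC_LO <- list(
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
          0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
          -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  db7 = c(0.00035371379997452024, -0.0018016407040474908,
          0.0004295779729213665, 0.01255099855609984, -0.01657454163066688,
          -0.03802993693501441, 0.08061260915108308, 0.07130921926683026,
          -0.22403618499387498, -0.14390600392856498, 0.4697822874051931,
          0.7291320908462351, 0.3965393194819173, 0.07785205408500918),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306, 0.5853546836542067,
          0.6756307362972898, 0.31287159091429995, 0.05441584224310401),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
           0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728),
  sym6 = c(0.015404109327027373, 0.0034907120842174702, -0.11799011114819057,
           -0.048311742585633, 0.4910559419267466, 0.787641141030194,
           0.3379294217276218, -0.07263752278646252, -0.021060292512300564,
           0.04472490177066578, 0.0017677118642428036, -0.007800708325034148),
  sym7 = c(0.002681814568257878, -0.0010473848886829163, -0.01263630340325193,
           0.03051551316596357, 0.0678926935013727, -0.049552834937127255,
           0.017441255086855827, 0.5361019170917628, 0.767764317003164,
           0.2886296317515146, -0.14004724044296152, -0.10780823770381774,
           0.004010244871533663, 0.010268176708511255),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605, -0.1432942383508097,
           -0.061273359067658524, 0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904, -0.027219029917056003,
           0.049137179673607506, 0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609),
  coif2 = c(-0.000720549445520347, -0.0018232088709110323,
            0.005611434819368834, 0.02368017194684777, -0.05943441864643109,
            -0.07648859907828076, 0.4170051844232391, 0.8127236354494135,
            0.3861100668227629, -0.0673725547237256, -0.04146493678687178,
            0.01638733646320364),
  coif3 = c(-3.459977319727278e-05, -7.0983302506379e-05,
            0.0004662169598204029, 0.0011175187708306303,
            -0.0025745176881367972, -0.009007976136730624,
            0.015880544863669452, 0.03455502757329774, -0.08230192710629983,
            -0.07179982161915484, 0.42848347637737, 0.7937772226260872,
            0.40517690240911824, -0.06112339000297255, -0.06577191128146936,
            0.023452696142077168, 0.007782596425672746,
            -0.003793512864380802),
  coif4 = c(-1.7849909144933469e-06, -3.259647940030751e-06,
            3.1229861599195265e-05, 6.233885431278719e-05,
            -0.0002599743371222568, -0.0005890202246332165,
            0.0012665610789256603, 0.0037514346971460866,
            -0.0056582838001308835, -0.015211728187697211,
            0.02508225333794961, 0.03933442260558915, -0.09622042453595264,
            -0.06662747236681717, 0.43438603311435653, 0.7822389344242826,
            0.41530842700068227, -0.05607731960356926, -0.08126671024919373,
            0.02668230466960483, 0.01606894713157503, -0.007346167936268051,
            -0.001629492425226786, 0.000892313902537003),
  coif5 = c(-9.604010112767894e-08, -1.6237995172048338e-07,
            2.0612203985788783e-06, 3.7007277113394796e-06,
            -2.1270221672515614e-05, -4.12198619242655e-05,
            0.00014035632812373243, 0.0003018579416682448,
            -0.0006375589261258812, -0.0016616273039298788,
            0.0024315754425382886, 0.006761520220620417,
            -0.009159507338676163, -0.019758391600965465,
            0.032674799467057355, 0.041287530472117834, -0.10556315130733723,
            -0.06203775157498196, 0.4379823066591634, 0.7742936228603274,
            0.42157126673075435, -0.052046670253554764, -0.09192158806008609,
            0.028169744270532353, 0.023408322118927783, -0.010131584846900276,
            -0.00415931262757864, 0.0021782943778456947, 0.0003585777411617577,
            -0.000212081862067494))

#' Available wavelet families
#' @return character vector of family names usable in the wavelet denoisers.
#' @export
wavelet_families <- function() names(WAVELET_DEC_LO)

wavelet_filters <- function(family) {
  h <- WAVELET_DEC_LO[[family]]
  if (is.null(h)) stop("unknown wavelet family `", family, "`")
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror filter
  list(lo = h, hi = g)
}

# one-level periodic analysis operators (n/2 x n); rows are shifts by 2 of
# the reversed filters, so T = rbind(lo, hi) is orthogonal
dwt_level_ops <- function(n, family) {
  f <- wavelet_filters(family)
  lo <- rev(f$lo); hi <- rev(f$hi)
  L <- length(lo)
  Glo <- matrix(0, n %/% 2L, n)
  Ghi <- matrix(0, n %/% 2L, n)
  for (i in seq_len(n %/% 2L)) {
    idx <- ((2L * (i - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (k in seq_len(L)) {
      Glo[i, idx[k]] <- Glo[i, idx[k]] + lo[k]
      Ghi[i, idx[k]] <- Ghi[i, idx[k]] + hi[k]
    }
  }
  list(lo = Glo, hi = Ghi)
}

.wavelet_cache <- new.env(parent = emptyenv())

# full multilevel analysis matrix W (n x n, orthogonal) for dyadic n.
# Coefficient layout: [cA_J, cD_J, ..., cD_1]; details start at n/2^level+1.
dwt_matrix <- function(n, family, level) {
  if (log2(n) %% 1 != 0) stop("dwt_matrix requires a power-of-two length")
  if (n %/% 2^level < 1L) stop("decomposition level too deep for length ", n)
  key <- paste(n, family, level, sep = "_")
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])
  W <- diag(n)
  nl <- n
  for (l in seq_len(level)) {
    ops <- dwt_level_ops(nl, family)
    W[seq_len(nl), ] <- rbind(ops$lo, ops$hi) %*% W[seq_len(nl), , drop = FALSE]
    nl <- nl %/% 2L
  }
  .wavelet_cache[[key]] <- W
  W
}

# symmetric (whole-sample) right-padding to length n_to
sym_pad_index <- function(n_from, n_to) {
  extra <- n_to - n_from
  if (extra == 0L) return(seq_len(n_from))
  if (extra > n_from - 1L) stop("padding longer than the signal")
  c(seq_len(n_from), n_from - seq_len(extra))
}

#' Wavelet shrinkage of a spectra matrix
#'
#' Core routine behind the 1-D wavelet denoisers: each row (spectrum) is
#' symmetrically padded to the next power of two, decomposed with an
#' orthogonal multilevel DWT, detail coefficients are thresholded at
#' `threshold_scale * sigma_hat * sqrt(2 log N)` (the universal threshold;
#' `sigma_hat` is the per-spectrum median absolute deviation of the
#' finest-level details divided by 0.6745), and reconstructed.
#'
#' @param x numeric matrix, spectra in rows.
#' @param family wavelet family, see [wavelet_families()].
#' @param level decomposition depth (>= 1).
#' @param rule `"soft"` (shrink toward zero) or `"hard"` (keep-or-kill).
#' @param threshold_scale multiplier on the universal threshold; 0 disables
#'   shrinkage and returns the input (up to reconstruction round-off).
#' @return matrix of the same shape as `x`.
#' @export
wavelet_shrink_rows <- function(x, family = "sym6", level = 5,
                                rule = c("soft", "hard"),
                                threshold_scale = 1) {
  rule <- match.arg(rule)
  if (threshold_scale < 0) stop("`threshold_scale` must be nonnegative")
  n0 <- ncol(x)
  n <- 2^ceiling(log2(n0))
  level <- min(level, floor(log2(n)))
  W <- dwt_matrix(n, family, level)
  xp <- x[, sym_pad_index(n0, n), drop = FALSE]
  D <- xp %*% t(W)
  na <- n %/% 2^level          # approximation coefficients stay untouched
  fine <- (n %/% 2L + 1L):n    # finest-level details estimate sigma
  sigma <- apply(abs(D[, fine, drop = FALSE]), 1L, stats::median) / 0.6745
  thr <- threshold_scale * sigma * sqrt(2 * log(n))
  det_idx <- (na + 1L):n
  Dd <- D[, det_idx, drop = FALSE]
  if (rule == "soft") {
    Dd <- sign(Dd) * pmax(abs(Dd) - thr, 0)
  } else {
    Dd <- Dd * (abs(Dd) > thr)
  }
  D[, det_idx] <- Dd
  (D %*% W)[, seq_len(n0), drop = FALSE]
}

# one-level 2-D analysis/synthesis helpers (periodic, orthogonal)
dwt2_forward <- function(img, ops) {
  lo <- ops$lo %*% img; hi <- ops$hi %*% img
  list(ll = lo %*% t(ops$lo), lh = lo %*% t(ops$hi),
       hl = hi %*% t(ops$lo), hh = hi %*% t(ops$hi))
}
dwt2_inverse <- function(sb, ops) {
  lo <- t(ops$lo) %*% sb$ll %*% ops$lo + t(ops$lo) %*% sb$lh %*% ops$hi
  hi <- t(ops$hi) %*% sb$hl %*% ops$lo + t(ops$hi) %*% sb$hh %*% ops$hi
  lo + hi
}

#' 2-D wavelet shrinkage of a square dyadic image
#'
#' Multilevel 2-D DWT with subband thresholding, used by
#' [wavelet2d_denoise()].  `sigma_hat` comes from the finest diagonal (HH)
#' subband; the universal threshold uses the padded pixel count.
#'
#' @param img square matrix with power-of-two side.
#' @inheritParams wavelet_shrink_rows
#' @return denoised matrix of the same shape.
#' @keywords internal
wavelet_shrink_image <- function(img, family = "sym6", level = 3,
                                 rule = c("soft", "hard"),
                                 threshold_scale = 1) {
  rule <- match.arg(rule)
  n <- nrow(img)
  if (ncol(img) != n || log2(n) %% 1 != 0)
    stop("image must be square with power-of-two side")
  level <- min(level, floor(log2(n)))
  subbands <- list()
  ll <- img
  for (l in seq_len(level)) {
    ops <- dwt_level_ops(nrow(ll), family)
    sb <- dwt2_forward(ll, ops)
    subbands[[l]] <- sb
    ll <- sb$ll
  }
  sigma <- stats::median(abs(subbands[[1L]]$hh)) / 0.6745
  thr <- threshold_scale * sigma * sqrt(2 * log(n * n))
  shrink <- function(d) {
    if (rule == "soft") sign(d) * pmax(abs(d) - thr, 0) else d * (abs(d) > thr)
  }
  for (l in seq_len(level)) {
    subbands[[l]]$lh <- shrink(subbands[[l]]$lh)
    subbands[[l]]$hl <- shrink(subbands[[l]]$hl)
    subbands[[l]]$hh <- shrink(subbands[[l]]$hh)
  }
  for (l in rev(seq_len(level))) {
    subbands[[l]]$ll <- ll
    ops <- dwt_level_ops(nrow(subbands[[l]]$ll) * 2L, family)
    ll <- dwt2_inverse(subbands[[l]], ops)
  }
  ll
}
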