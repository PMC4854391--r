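## Published SDQ parameter and endorsement tables for Norwegian 16-18-year-olds
## (population survey; girls are the reference group).  These constants
## parameterize the synthetic-data presets and the desk-check utilities.

#' Published sample sizes and participation counts
#'
#' @return named list: \code{n_girls} (5399), \code{n_boys} (4854),
#'   \code{n_participants} (10254), \code{n_target} (19430).
#' @export
sdq_published_n <- function() {
  list(n_girls = 5399L, n_boys = 4854L,
       n_participants = 10254L, n_target = 19430L)
}

#' Published standardized loadings and thresholds
#'
#' Standardized factor loadings and probit thresholds per item and gender from
#' the multigroup partial-invariance solution, together with the flag for the
#' eight items showing differential item functioning (DIF) by gender.
#'
#' @return data.frame: \code{item_id}, \code{scale}, \code{dif},
#'   \code{loading_g}, \code{t1_g}, \code{t2_g} (girls),
#'   \code{loading_b}, \code{t1_b}, \code{t2_b} (boys).
#' @export
sdq_published_loadings <- function() {
  x <- read.csv(text = "
item_id,dif,loading_g,t1_g,t2_g,loading_b,t1_b,t2_b
somatic,0,0.578,-0.205,0.783,0.559,-0.210,0.804
worries,0,0.670,-0.610,0.607,0.589,-0.569,0.566
unhappy,1,0.814,0.012,1.117,0.822,-0.085,0.801
clingy,1,0.595,-0.671,0.665,0.560,-0.867,0.478
afraid,1,0.650,0.277,1.321,0.748,0.230,1.133
tantrum,1,0.412,-0.025,1.231,0.359,0.364,1.590
obeys,1,0.571,0.028,1.909,0.552,0.538,2.406
fights,0,0.622,1.647,2.401,0.696,2.114,3.083
lies,0,0.621,1.403,2.141,0.650,1.685,2.572
steals,0,0.471,1.418,2.089,0.532,1.838,2.708
restless,0,0.517,-0.519,0.976,0.439,-0.466,0.875
fidgety,0,0.496,-0.107,1.236,0.456,-0.104,1.201
distractible,0,0.755,-0.559,0.719,0.731,-0.572,0.736
reflective,1,0.468,-0.476,1.602,0.499,-0.419,1.422
attends,0,0.710,-0.643,1.010,0.674,-0.645,1.013
loner,0,0.573,0.022,1.305,0.499,0.021,1.217
friend,0,0.745,1.149,1.998,0.737,1.217,2.117
popular,0,0.706,0.255,1.821,0.673,0.260,1.859
bullied,1,0.628,1.439,2.217,0.775,1.427,2.275
oldbest,0,0.422,0.264,1.406,0.418,0.280,1.491
considerate,0,0.806,-2.611,-1.178,0.792,-2.374,-1.071
shares,0,0.475,-1.794,-0.228,0.518,-1.810,-0.230
caring,1,0.607,-2.217,-0.878,0.635,-1.940,-0.331
kind,0,0.650,-1.993,-0.731,0.710,-2.017,-0.740
helpout,0,0.479,-1.402,0.495,0.504,-1.366,0.483
", stringsAsFactors = FALSE)
  meta <- sdq_item_meta()
  x$scale <- meta$scale[match(x$item_id, meta$item_id)]
  x$dif <- as.logical(x$dif)
  x[, c("item_id", "scale", "dif", "loading_g", "t1_g", "t2_g",
        "loading_b", "t1_b", "t2_b")]
}

#' Published latent-factor correlations per gender
#'
#' @return list of two 5x5 correlation matrices, \code{girls} and \code{boys},
#'   dimnames = subscales.
#' @export
sdq_published_phi <- function() {
  sc <- sdq_scales()
  girls <- boys <- diag(5)
  dimnames(girls) <- dimnames(boys) <- list(sc, sc)
  gv <- c(.310, .525, .577, -.097, .799, .502, -.622, .245, -.341, -.512)
  bv <- c(.488, .534, .671, -.092, .790, .568, -.569, .261, -.294, -.506)
  k <- 0L
  for (i in 1:4) for (j in (i + 1):5) {
    k <- k + 1L
    girls[i, j] <- girls[j, i] <- gv[k]
    boys[i, j] <- boys[j, i] <- bv[k]
  }
  list(girls = girls, boys = boys)
}

#' Published latent mean differences (boys minus girls) and Cohen's d
#'
#' Girls' latent means are fixed at zero; \code{kappa_nodif}/\code{d_nodif}
#' come from the model ignoring DIF and \code{kappa_dif}/\code{d_dif} from the
#' model accounting for it.
#'
#' @return data.frame with one row per subscale.
#' @export
sdq_published_latent_means <- function() {
  data.frame(
    scale = sdq_scales(),
    kappa_nodif = c(-0.61, 0.11, -0.10, 0.07, -0.50),
    d_nodif     = c(1.062, 0.280, 0.188, 0.116, 0.622),
    kappa_dif   = c(-0.65, 0.43, -0.09, 0.07, -0.37),
    d_dif       = c(1.147, 1.113, 0.181, 0.117, 0.439),
    stringsAsFactors = FALSE
  )
}

#' Published modification constants of the five-factor model
#'
#' @return list: \code{cross_loading} (tantrum on emotion, 0.353) and
#'   \code{residual_cor} (restless-fidgety .555, distractible-attends .332).
#' @export
sdq_published_modifications <- function() {
  list(
    cross_loading = c(item = "tantrum", factor = "emotion", value = "0.353"),
    cross_loading_value = 0.353,
    residual_cor = data.frame(
      item1 = c("restless", "distractible"),
      item2 = c("fidgety", "attends"),
      value = c(0.555, 0.332),
      stringsAsFactors = FALSE
    )
  )
}

#' Published endorsement rates (percent per category)
#'
#' @return data.frame: \code{item_id}, then \code{full0..2}, \code{boys0..2},
#'   \code{girls0..2} percentages.
#' @export
sdq_published_endorsement <- function() {
  read.csv(text = "
item_id,full0,boys0,girls0,full1,boys1,girls1,full2,boys2,girls2
somatic,53.88,69.11,40.33,31.3,23.63,38.12,14.82,7.26,21.55
worries,40.21,54.22,27.77,40.54,34.97,45.50,19.25,10.81,26.72
unhappy,64.97,81.28,50.47,26.26,14.92,36.33,8.78,3.80,13.20
clingy,33.01,41.93,25.10,47.62,45.39,49.59,19.37,12.69,25.31
afraid,73.09,86.78,60.91,20.96,11.04,29.77,5.96,2.17,9.32
tantrum,53.88,59.74,49.01,36.84,33.21,40.08,9.09,7.05,10.92
obeys,3.40,4.07,2.81,48.34,50.91,46.07,48.25,45.02,51.11
fights,92.63,89.96,94.99,6.36,8.80,4.20,1.01,1.24,0.81
lies,87.12,82.12,91.56,10.30,14.19,6.85,2.58,3.69,1.59
steals,90.46,88.22,92.44,7.70,9.67,5.94,1.85,2.11,1.61
restless,32.47,35.07,30.17,50.83,47.51,53.77,16.70,17.42,16.06
fidgety,47.4,48.59,46.33,42.2,41.28,43.03,10.40,10.14,10.63
distractible,30.84,34.26,27.80,47.63,47.95,47.33,21.54,17.78,24.87
reflective,5.94,6.49,5.46,59.76,56.30,62.84,34.30,37.21,31.70
attends,14.26,13.24,15.17,57.79,57.88,57.71,27.95,28.89,27.13
loner,49.68,47.31,51.79,39.49,41.30,37.87,10.84,11.39,10.34
friend,2.20,2.30,2.12,10.51,11.08,10.01,87.28,86.62,87.87
popular,3.58,4.16,3.06,37.77,37.94,37.63,58.65,57.90,59.31
bullied,91.74,90.88,92.50,6.87,7.66,6.17,1.39,1.46,1.33
oldbest,59.76,59.63,59.87,32.48,33.14,31.90,7.76,7.22,8.23
considerate,1.15,1.71,0.66,16.12,22.61,10.36,82.73,75.68,88.98
shares,4.56,5.85,3.41,40.45,43.56,37.70,54.99,50.59,58.89
caring,2.93,4.73,1.33,29.47,42.77,17.67,67.60,52.50,81.00
kind,3.22,3.84,2.66,24.62,29.31,20.46,72.17,66.85,76.88
helpout,10.11,12.41,8.08,62.02,62.51,61.57,27.87,25.08,30.35
", stringsAsFactors = FALSE)
}
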