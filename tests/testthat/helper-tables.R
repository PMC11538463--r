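# Published reference values of the patient-triage case study, keyed in from
# the printed tables. Each collective cell is (linguistic value, mu, nu).

published <- local({
  t4 <- list(  # collective matrix, PMSM route
    list(c(1.3168, .8796, .2415), c(1.5339, .8171, .2991),
         c(1.6554, .8326, .2924), c(1.6099, .8735, .2093)),
    list(c(1.0381, .8929, .2348), c(1.4579, .8749, .2295),
         c(1.2364, .9162, .1942), c(1.6672, .9185, .3314)),
    list(c(1.3495, .9011, .1420), c(1.0451, .9455, .2347),
         c(1.5723, .8303, .0867), c(1.5487, .8946, .0950)),
    list(c(1.0195, .8822, .2127), c(1.3674, .8965, .1637),
         c(1.5964, .8709, .2378), c(1.3364, .8838, .1307)),
    list(c(1.6750, .8453, .2623), c(1.2793, .9129, .1944),
         c(1.0501, .9153, .1633), c(1.5381, .9048, .2460)))
  t5 <- list(  # collective matrix, dual (PDMSM) route
    list(c(0.7135, .3898, .8256), c(1.0642, .2885, .8077),
         c(1.0774, .3526, .7835), c(1.1164, .4331, .7414)),
    list(c(0.3563, .3106, .8493), c(0.8014, .4045, .7517),
         c(0.4180, .4625, .7943), c(1.3896, .5618, .7780)),
    list(c(0.8066, .4527, .7893), c(0.3735, .4948, .8701),
         c(1.2081, .4136, .5964), c(0.9190, .4799, .6492)),
    list(c(0.2796, .2220, .8658), c(0.5567, .4649, .7863),
         c(1.0039, .3963, .7482), c(0.7593, .4009, .7173)),
    list(c(1.3417, .3833, .7711), c(0.5038, .3107, .8071),
         c(0.4376, .4253, .7780), c(1.1233, .5101, .7292)))
  # components of t4 whose printed value is inconsistent with the rest of the
  # table (the other two components of the same cell, and the whole dual
  # table, match the recomputation to 4 decimals); 1 = linguistic, 2 = mu,
  # 3 = nu, followed by the recomputed value
  t4_misprints <- list(
    list(i = 3, j = 1, comp = 3, computed = 0.164415),
    list(i = 3, j = 3, comp = 2, computed = 0.759156),
    list(i = 5, j = 1, comp = 1, computed = 1.669747),
    list(i = 5, j = 2, comp = 2, computed = 0.875864))
  # theta-scan endpoints (5-decimal rows): theta = 1 gives the prioritized
  # sum-model scores, theta = 0 the product-model scores
  psm <- c(0.14965, 0.14271, 0.15050, 0.14188, 0.15804)
  ppm <- c(0.00555, 0.00469, 0.00597, 0.00450, 0.00715)
  # q-scan of the combined measure at theta = 0.5 (4 decimals)
  qscan <- list(
    `3` = c(0.0776, 0.0737, 0.0782, 0.0732, 0.0826),
    `5` = c(0.0767, 0.0732, 0.0774, 0.0728, 0.0821),
    `7` = c(0.0758, 0.0726, 0.0768, 0.0721, 0.0814),
    `9` = c(0.0750, 0.0720, 0.0762, 0.0715, 0.0809),
    `11` = c(0.0743, 0.0716, 0.0758, 0.0711, 0.0804),
    `13` = c(0.0737, 0.0711, 0.0754, 0.0706, 0.0801),
    `15` = c(0.0732, 0.0708, 0.0750, 0.0704, 0.0800))
  qscan_dual <- list(
    `3` = c(0.0625, 0.0569, 0.0645, 0.0555, 0.0710),
    `5` = c(0.0617, 0.0566, 0.0637, 0.0556, 0.0699),
    `7` = c(0.0607, 0.0562, 0.0632, 0.0553, 0.0688),
    `9` = c(0.0602, 0.0559, 0.0624, 0.0551, 0.0680),
    `11` = c(0.0598, 0.0557, 0.0621, 0.0548, 0.0674),
    `13` = c(0.0592, 0.0553, 0.0618, 0.0546, 0.0669),
    `15` = c(0.0588, 0.0551, 0.0616, 0.0545, 0.0664))
  # dual-route WASPAS measures at theta = 0.5 (only P1 and P5 are
  # arithmetically consistent across the published tables)
  dual_combined_p1p5 <- c(0.0625, 0.0710)
  # pairwise deviation table of the PROMETHEE comparison: ordered pairs
  # (1,2),(1,3),...,(5,4) by rows, criteria by columns
  t12 <- matrix(c(
    1.5124, 0.0000, 1.3771, 0.0000,
    0.0000, 1.4568, 0.3521, 0.0420,
    1.7063, 0.0000, 0.0000, 1.4499,
    0.0000, 0.3028, 2.5221, 0.0528,
    0.0000, 0.3069, 0.0000, 0.8057,
    0.0000, 1.7637, 0.0000, 0.8478,
    0.1939, 0.2438, 0.0000, 2.2557,
    0.0000, 0.6097, 1.1449, 0.8585,
    0.4821, 0.0000, 0.0000, 0.0000,
    1.9945, 0.0000, 1.0251, 0.0000,
    2.1884, 0.0000, 0.0000, 1.4079,
    0.0000, 0.0000, 2.1699, 0.0000,
    0.0000, 0.0631, 0.2053, 0.0000,
    0.0000, 0.0000, 1.5826, 0.0000,
    0.0000, 1.5199, 0.5574, 0.0000,
    0.0000, 0.3659, 2.7274, 0.0000,
    1.6088, 0.0000, 0.0000, 0.0000,
    3.1212, 0.0000, 0.0000, 0.0000,
    1.1267, 1.1540, 0.0000, 0.0108,
    3.3151, 0.0000, 0.0000, 1.3971), byrow = TRUE, ncol = 4)
  net_flow_p1 <- 0.1789
  promethee_ranking <- c(1L, 5L, 3L, 2L, 4L)
  muirhead_scores <- c(0.1748, 0.1643, 0.1672, 0.1586, 0.1674)
  muirhead_ranking <- c(1L, 5L, 3L, 2L, 4L)
  qrofmsm_scores <- c(0.8000, 0.8502, 0.8578, 0.8415, 0.8543)
  qrofmsm_ranking <- c(3L, 5L, 2L, 4L, 1L)
  waspas_ranking <- c(5L, 3L, 1L, 2L, 4L)
  list(t4 = t4, t5 = t5, t4_misprints = t4_misprints, psm = psm, ppm = ppm,
       qscan = qscan, qscan_dual = qscan_dual,
       dual_combined_p1p5 = dual_combined_p1p5, t12 = t12,
       net_flow_p1 = net_flow_p1, promethee_ranking = promethee_ranking,
       muirhead_scores = muirhead_scores, muirhead_ranking = muirhead_ranking,
       qrofmsm_scores = qrofmsm_scores, qrofmsm_ranking = qrofmsm_ranking,
       waspas_ranking = waspas_ranking)
})
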