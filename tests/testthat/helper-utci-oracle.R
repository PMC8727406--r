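# Independent reference evaluation of the operational UTCI polynomial:
# the offset written out term by term, used as the oracle against the
# package's table-driven evaluation. ta degC, va m/s (10 m),
# dtmrt = tmrt - ta degC, vp hPa.
utci_oracle <- function(ta, tmrt, va, vp) {
  d <- tmrt - ta
  pa <- vp / 10
  off <-
    0.607562052 +
    -0.0227712343 * ta +
    0.000806470249 * ta^2 +
    -0.000154271372 * ta^3 +
    -3.24651735e-06 * ta^4 +
    7.32602852e-08 * ta^5 +
    1.35959073e-09 * ta^6 +
    -2.2583652 * va +
    0.0880326035 * ta * va +
    0.00216844454 * ta^2 * va +
    -1.53347087e-05 * ta^3 * va +
    -5.72983704e-07 * ta^4 * va +
    -2.55090145e-09 * ta^5 * va +
    -0.751269505 * va^2 +
    -0.00408350271 * ta * va^2 +
    -5.21670675e-05 * ta^2 * va^2 +
    1.94544667e-06 * ta^3 * va^2 +
    1.14099531e-08 * ta^4 * va^2 +
    0.158137256 * va^3 +
    -6.57263143e-05 * ta * va^3 +
    2.22697524e-07 * ta^2 * va^3 +
    -4.16117031e-08 * ta^3 * va^3 +
    -0.0127762753 * va^4 +
    9.66891875e-06 * ta * va^4 +
    2.52785852e-09 * ta^2 * va^4 +
    0.000456306672 * va^5 +
    -1.74202546e-07 * ta * va^5 +
    -5.91491269e-06 * va^6 +
    0.398374029 * d +
    0.000183945314 * ta * d +
    -0.00017375451 * ta^2 * d +
    -7.60781159e-07 * ta^3 * d +
    3.77830287e-08 * ta^4 * d +
    5.43079673e-10 * ta^5 * d +
    -0.0200518269 * va * d +
    0.000892859837 * ta * va * d +
    3.45433048e-06 * ta^2 * va * d +
    -3.77925774e-07 * ta^3 * va * d +
    -1.69699377e-09 * ta^4 * va * d +
    0.000169992415 * va^2 * d +
    -4.99204314e-05 * ta * va^2 * d +
    2.47417178e-07 * ta^2 * va^2 * d +
    1.07596466e-08 * ta^3 * va^2 * d +
    8.49242932e-05 * va^3 * d +
    1.35191328e-06 * ta * va^3 * d +
    -6.21531254e-09 * ta^2 * va^3 * d +
    -4.99410301e-06 * va^4 * d +
    -1.89489258e-08 * ta * va^4 * d +
    8.15300114e-08 * va^5 * d +
    0.00075504309 * d^2 +
    -5.65095215e-05 * ta * d^2 +
    -4.52166564e-07 * ta^2 * d^2 +
    2.46688878e-08 * ta^3 * d^2 +
    2.42674348e-10 * ta^4 * d^2 +
    0.00015454725 * va * d^2 +
    5.2411097e-06 * ta * va * d^2 +
    -8.75874982e-08 * ta^2 * va * d^2 +
    -1.50743064e-09 * ta^3 * va * d^2 +
    -1.56236307e-05 * va^2 * d^2 +
    -1.33895614e-07 * ta * va^2 * d^2 +
    2.49709824e-09 * ta^2 * va^2 * d^2 +
    6.51711721e-07 * va^3 * d^2 +
    1.94960053e-09 * ta * va^3 * d^2 +
    -1.00361113e-08 * va^4 * d^2 +
    -1.21206673e-05 * d^3 +
    -2.1820366e-07 * ta * d^3 +
    7.51269482e-09 * ta^2 * d^3 +
    9.79063848e-11 * ta^3 * d^3 +
    1.25006734e-06 * va * d^3 +
    -1.81584736e-09 * ta * va * d^3 +
    -3.52197671e-10 * ta^2 * va * d^3 +
    -3.3651463e-08 * va^2 * d^3 +
    1.35908359e-10 * ta * va^2 * d^3 +
    4.1703262e-10 * va^3 * d^3 +
    -1.30369025e-09 * d^4 +
    4.13908461e-10 * ta * d^4 +
    9.22652254e-12 * ta^2 * d^4 +
    -5.08220384e-09 * va * d^4 +
    -2.24730961e-11 * ta * va * d^4 +
    1.17139133e-10 * va^2 * d^4 +
    6.62154879e-10 * d^5 +
    4.0386326e-13 * ta * d^5 +
    1.95087203e-12 * va * d^5 +
    -4.73602469e-12 * d^6 +
    5.12733497 * pa +
    -0.312788561 * ta * pa +
    -0.0196701861 * ta^2 * pa +
    0.00099969087 * ta^3 * pa +
    9.51738512e-06 * ta^4 * pa +
    -4.66426341e-07 * ta^5 * pa +
    0.548050612 * va * pa +
    -0.00330552823 * ta * va * pa +
    -0.0016411944 * ta^2 * va * pa +
    -5.16670694e-06 * ta^3 * va * pa +
    9.52692432e-07 * ta^4 * va * pa +
    -0.0429223622 * va^2 * pa +
    0.00500845667 * ta * va^2 * pa +
    1.00601257e-06 * ta^2 * va^2 * pa +
    -1.81748644e-06 * ta^3 * va^2 * pa +
    -0.00125813502 * va^3 * pa +
    -0.000179330391 * ta * va^3 * pa +
    2.34994441e-06 * ta^2 * va^3 * pa +
    0.000129735808 * va^4 * pa +
    1.2906487e-06 * ta * va^4 * pa +
    -2.28558686e-06 * va^5 * pa +
    -0.0369476348 * d * pa +
    0.00162325322 * ta * d * pa +
    -3.1427968e-05 * ta^2 * d * pa +
    2.59835559e-06 * ta^3 * d * pa +
    -4.77136523e-08 * ta^4 * d * pa +
    0.0086420339 * va * d * pa +
    -0.000687405181 * ta * va * d * pa +
    -9.13863872e-06 * ta^2 * va * d * pa +
    5.15916806e-07 * ta^3 * va * d * pa +
    -3.59217476e-05 * va^2 * d * pa +
    3.28696511e-05 * ta * va^2 * d * pa +
    -7.10542454e-07 * ta^2 * va^2 * d * pa +
    -1.243823e-05 * va^3 * d * pa +
    -7.385844e-09 * ta * va^3 * d * pa +
    2.20609296e-07 * va^4 * d * pa +
    -0.00073246918 * d^2 * pa +
    -1.87381964e-05 * ta * d^2 * pa +
    4.80925239e-06 * ta^2 * d^2 * pa +
    -8.7549204e-08 * ta^3 * d^2 * pa +
    2.7786293e-05 * va * d^2 * pa +
    -5.06004592e-06 * ta * va * d^2 * pa +
    1.14325367e-07 * ta^2 * va * d^2 * pa +
    2.53016723e-06 * va^2 * d^2 * pa +
    -1.72857035e-08 * ta * va^2 * d^2 * pa +
    -3.95079398e-08 * va^3 * d^2 * pa +
    -3.59413173e-07 * d^3 * pa +
    7.04388046e-07 * ta * d^3 * pa +
    -1.89309167e-08 * ta^2 * d^3 * pa +
    -4.79768731e-07 * va * d^3 * pa +
    7.96079978e-09 * ta * va * d^3 * pa +
    1.62897058e-09 * va^2 * d^3 * pa +
    3.94367674e-08 * d^4 * pa +
    -1.18566247e-09 * ta * d^4 * pa +
    3.34678041e-10 * va * d^4 * pa +
    -1.15606447e-10 * d^5 * pa +
    -2.80626406 * pa^2 +
    0.548712484 * ta * pa^2 +
    -0.0039942841 * ta^2 * pa^2 +
    -0.000954009191 * ta^3 * pa^2 +
    1.93090978e-05 * ta^4 * pa^2 +
    -0.308806365 * va * pa^2 +
    0.0116952364 * ta * va * pa^2 +
    0.000495271903 * ta^2 * va * pa^2 +
    -1.90710882e-05 * ta^3 * va * pa^2 +
    0.00210787756 * va^2 * pa^2 +
    -0.000698445738 * ta * va^2 * pa^2 +
    2.30109073e-05 * ta^2 * va^2 * pa^2 +
    0.00041785659 * va^3 * pa^2 +
    -1.27043871e-05 * ta * va^3 * pa^2 +
    -3.04620472e-06 * va^4 * pa^2 +
    0.0514507424 * d * pa^2 +
    -0.00432510997 * ta * d * pa^2 +
    8.99281156e-05 * ta^2 * d * pa^2 +
    -7.14663943e-07 * ta^3 * d * pa^2 +
    -0.000266016305 * va * d * pa^2 +
    0.000263789586 * ta * va * d * pa^2 +
    -7.01199003e-06 * ta^2 * va * d * pa^2 +
    -0.000106823306 * va^2 * d * pa^2 +
    3.61341136e-06 * ta * va^2 * d * pa^2 +
    2.29748967e-07 * va^3 * d * pa^2 +
    0.000304788893 * d^2 * pa^2 +
    -6.42070836e-05 * ta * d^2 * pa^2 +
    1.16257971e-06 * ta^2 * d^2 * pa^2 +
    7.68023384e-06 * va * d^2 * pa^2 +
    -5.47446896e-07 * ta * va * d^2 * pa^2 +
    -3.5993791e-08 * va^2 * d^2 * pa^2 +
    -4.36497725e-06 * d^3 * pa^2 +
    1.68737969e-07 * ta * d^3 * pa^2 +
    2.67489271e-08 * va * d^3 * pa^2 +
    3.23926897e-09 * d^4 * pa^2 +
    -0.0353874123 * pa^3 +
    -0.22120119 * ta * pa^3 +
    0.0155126038 * ta^2 * pa^3 +
    -0.000263917279 * ta^3 * pa^3 +
    0.0453433455 * va * pa^3 +
    -0.00432943862 * ta * va * pa^3 +
    0.000145389826 * ta^2 * va * pa^3 +
    0.00021750861 * va^2 * pa^3 +
    -6.66724702e-05 * ta * va^2 * pa^3 +
    3.3321714e-05 * va^3 * pa^3 +
    -0.00226921615 * d * pa^3 +
    0.000380261982 * ta * d * pa^3 +
    -5.45314314e-09 * ta^2 * d * pa^3 +
    -0.000796355448 * va * d * pa^3 +
    2.53458034e-05 * ta * va * d * pa^3 +
    -6.31223658e-06 * va^2 * d * pa^3 +
    0.000302122035 * d^2 * pa^3 +
    -4.77403547e-06 * ta * d^2 * pa^3 +
    1.73825715e-06 * va * d^2 * pa^3 +
    -4.09087898e-07 * d^3 * pa^3 +
    0.614155345 * pa^4 +
    -0.0616755931 * ta * pa^4 +
    0.00133374846 * ta^2 * pa^4 +
    0.00355375387 * va * pa^4 +
    -0.000513027851 * ta * va * pa^4 +
    0.000102449757 * va^2 * pa^4 +
    -0.00148526421 * d * pa^4 +
    -4.11469183e-05 * ta * d * pa^4 +
    -6.80434415e-06 * va * d * pa^4 +
    -9.77675906e-06 * d^2 * pa^4 +
    0.0882773108 * pa^5 +
    -0.00301859306 * ta * pa^5 +
    0.00104452989 * va * pa^5 +
    0.000247090539 * d * pa^5 +
    0.00148348065 * pa^6
  ta + off
}
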