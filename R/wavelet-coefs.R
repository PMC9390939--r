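# Orthonormal scaling (lowpass decomposition) filter coefficients for the
# Daubechies, symlet and coiflet families used by the wavelet denoisers.
# Highpass and reconstruction filters are derived by quadrature-mirror rules.
.wavelet_lowpass <- list(
  db3 = c(
    3.5226291885709533e-02, -8.5441273882026658e-02, -1.3501102001025458e-01, 4.5987750211849154e-01,
    8.0689150931109255e-01, 3.3267055295008263e-01
  ),
  db4 = c(
    -1.0597401785069032e-02, 3.2883011666885197e-02, 3.0841381835560764e-02, -1.8703481171909309e-01,
    -2.7983769416859854e-02, 6.3088076792985892e-01, 7.1484657055291567e-01, 2.3037781330889651e-01
  ),
  db5 = c(
    3.3357252854737712e-03, -1.2580751999081999e-02, -6.2414902127982744e-03, 7.7571493840045719e-02,
    -3.2244869584638375e-02, -2.4229488706638203e-01, 1.3842814590132074e-01, 7.2430852843777294e-01,
    6.0382926979718965e-01, 1.6010239797419293e-01
  ),
  db6 = c(
    -1.0773010853084796e-03, 4.7772575109455108e-03, 5.5384220116149613e-04, -3.1582039317486030e-02,
    2.7522865530305727e-02, 9.7501605587323043e-02, -1.2976686756726194e-01, -2.2626469396543983e-01,
    3.1525035170919763e-01, 7.5113390802109536e-01, 4.9462389039845306e-01, 1.1154074335010947e-01
  ),
  sym3 = c(
    3.5226291882100656e-02, -8.5441273882241486e-02, -1.3501102001039084e-01, 4.5987750211933132e-01,
    8.0689150931333875e-01, 3.3267055295095688e-01
  ),
  sym4 = c(
    -7.5765714789273325e-02, -2.9635527645998510e-02, 4.9761866763201545e-01, 8.0373875180591614e-01,
    2.9785779560527736e-01, -9.9219543576847216e-02, -1.2603967262037833e-02, 3.2223100604042702e-02
  ),
  sym5 = c(
    2.7333068345077982e-02, 2.9519490925774643e-02, -3.9134249302383094e-02, 1.9939753397739360e-01,
    7.2340769040242059e-01, 6.3397896345821192e-01, 1.6602105764522319e-02, -1.7532808990845047e-01,
    -2.1101834024758855e-02, 1.9538882735286728e-02
  ),
  sym6 = c(
    1.5404109327027373e-02, 3.4907120842174702e-03, -1.1799011114819057e-01, -4.8311742585632998e-02,
    4.9105594192674662e-01, 7.8764114103019400e-01, 3.3792942172762180e-01, -7.2637522786462516e-02,
    -2.1060292512300564e-02, 4.4724901770665779e-02, 1.7677118642428036e-03, -7.8007083250341480e-03
  ),
  coif3 = c(
    -3.4599773197272781e-05, -7.0983302506379004e-05, 4.6621695982040288e-04, 1.1175187708306303e-03,
    -2.5745176881367972e-03, -9.0079761367306242e-03, 1.5880544863669452e-02, 3.4555027573297738e-02,
    -8.2301927106299827e-02, -7.1799821619154838e-02, 4.2848347637737000e-01, 7.9377722262608719e-01,
    4.0517690240911824e-01, -6.1123390002972552e-02, -6.5771911281469364e-02, 2.3452696142077168e-02,
    7.7825964256727463e-03, -3.7935128643808019e-03
  ),
  coif4 = c(
    -1.7849909144933469e-06, -3.2596479400307510e-06, 3.1229861599195265e-05, 6.2338854312787192e-05,
    -2.5997433712225682e-04, -5.8902022463321654e-04, 1.2665610789256603e-03, 3.7514346971460866e-03,
    -5.6582838001308835e-03, -1.5211728187697211e-02, 2.5082253337949612e-02, 3.9334422605589149e-02,
    -9.6220424535952642e-02, -6.6627472366817167e-02, 4.3438603311435653e-01, 7.8223893442428261e-01,
    4.1530842700068227e-01, -5.6077319603569258e-02, -8.1266710249193727e-02, 2.6682304669604830e-02,
    1.6068947131575029e-02, -7.3461679362680507e-03, -1.6294924252267860e-03, 8.9231390253700297e-04
  ),
  coif5 = c(
    -9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06,
    -2.1270221672515614e-05, -4.1219861924265501e-05, 1.4035632812373243e-04, 3.0185794166824478e-04,
    -6.3755892612588115e-04, -1.6616273039298788e-03, 2.4315754425382886e-03, 6.7615202206204169e-03,
    -9.1595073386761625e-03, -1.9758391600965465e-02, 3.2674799467057355e-02, 4.1287530472117834e-02,
    -1.0556315130733723e-01, -6.2037751574981960e-02, 4.3798230665916338e-01, 7.7429362286032744e-01,
    4.2157126673075435e-01, -5.2046670253554764e-02, -9.1921588060086087e-02, 2.8169744270532353e-02,
    2.3408322118927783e-02, -1.0131584846900276e-02, -4.1593126275786402e-03, 2.1782943778456947e-03,
    3.5857774116175768e-04, -2.1208186206749400e-04
  )
)
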