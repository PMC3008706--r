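{
  "class": "blobslice.ShapeModel",
  "member_mean": [0.0346320346320346, 0.0539525820306311, -0.215798936919628, -0.424610319688113, 0.0433657062053036, -0.182241016031845, -0.343906120888955],
  "member_cov": [2.34672149444758, 0.00560200491400802, -0.0437465053662626, -0.0498646232560965, -0.00139775257958324, -0.0266044154836924, -0.0174573075657342, 0.00560200491400802, 0.0109335495523065, -0.00137868357907302, -0.000321128370996634, 0.0084400695026833, -0.000324653900302148, 4.14763334688777e-05, -0.0437465053662626, -0.00137868357907302, 0.0551896894393071, 0.0663150830220657, 0.00128313754615744, 0.043975867052158, 0.0457002629156509, -0.0498646232560965, -0.000321128370996634, 0.0663150830220657, 0.152833967971078, 0.00328185155253033, 0.0484899460427857, 0.106861701832689, -0.00139775257958324, 0.0084400695026833, 0.00128313754615744, 0.00328185155253033, 0.00921590740449716, 0.00141921639585472, 0.00264332213558064, -0.0266044154836924, -0.000324653900302148, 0.043975867052158, 0.0484899460427857, 0.00141921639585472, 0.0371248148241241, 0.0338461259345747, -0.0174573075657342, 4.14763334688777e-05, 0.0457002629156509, 0.106861701832689, 0.00264332213558064, 0.0338461259345747, 0.0793615271683585],
  "distractor_mean": [-0.0689655172413793, 1.4570492972153, -0.068990386399686, -0.0975356900912763, 0.875409082806191, -0.0327683020811058, -0.0421886961952666],
  "distractor_cov": [4.85696402081978, -0.0467095341253499, 0.0150417588817209, 0.0876506477833154, -0.0215452861310997, 0.0324922414903596, 0.0385349588659542, -0.0467095341253499, 0.208312843821802, 0.0341160419419569, 0.0359914540494559, 0.135888874982188, 0.0126468760553448, 0.0169154548944336, 0.0150417588817209, 0.0341160419419569, 0.0462750462892075, 0.0554328528700627, 0.019190018657757, 0.0278823688563818, 0.0319896121073309, 0.0876506477833154, 0.0359914540494559, 0.0554328528700627, 0.194106172518871, 0.0113446571512665, 0.0344110265595322, 0.0989131811771904, -0.0215452861310997, 0.135888874982188, 0.019190018657757, 0.0113446571512665, 0.716060683649449, 0.0385014456163022, 0.0404870262569596, 0.0324922414903596, 0.0126468760553448, 0.0278823688563818, 0.0344110265595322, 0.0385014456163022, 0.0336648859574215, 0.0333465206888476, 0.0385349588659542, 0.0169154548944336, 0.0319896121073309, 0.0989131811771904, 0.0404870262569596, 0.0333465206888476, 0.0960846145540614],
  "priors": {
    "member": 0.42,
    "distractor": 0.58
  },
  "n_training": {
    "member": 231,
    "distractor": 319
  },
  "regularization": 0.0001
}
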