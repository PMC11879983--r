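# Generated by tools/generate_dynamics.py -- do not edit by hand.
# Planar 7-segment skeleton: implicit dynamics residual, contact-point
# kinematics and virtual-sensor kinematics with analytic Jacobians.
# All functions are vectorized over evaluation points (matrix columns).

.dyn_eom <- function(q, v, a, tau, f, p) {
  n <- ncol(q)
  out <- list(res = matrix(0, n, 9L), Jq = array(0, c(n, 9L, 9L)),
              Jv = array(0, c(n, 9L, 9L)), Ja = array(0, c(n, 9L, 9L)),
              Jf = array(0, c(n, 9L, 8L)))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  tau1 <- tau[1L, ]
  tau2 <- tau[2L, ]
  tau3 <- tau[3L, ]
  tau4 <- tau[4L, ]
  tau5 <- tau[5L, ]
  tau6 <- tau[6L, ]
  fx1 <- f[1L, ]
  fy1 <- f[2L, ]
  fx2 <- f[3L, ]
  fy2 <- f[4L, ]
  fx3 <- f[5L, ]
  fy3 <- f[6L, ]
  fx4 <- f[7L, ]
  fy4 <- f[8L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- cos(q3)
  w1 <- cHAT*mHAT
  w2 <- w0*w1
  w3 <- v3^2
  w4 <- sin(q3)
  w5 <- q3 + q4
  w6 <- sin(w5)
  w7 <- LTH*w6
  w8 <- mFT*w7
  w9 <- v4^2
  w10 <- mSH*w7
  w11 <- cTH*mTH
  w12 <- w11*w6
  w13 <- cos(w5)
  w14 <- 2*mFT
  w15 <- v3*w14
  w16 <- w15*w7
  w17 <- v4*w16
  w18 <- 2*mSH
  w19 <- v3*w18
  w20 <- w19*w7
  w21 <- v4*w20
  w22 <- 2*mTH
  w23 <- cTH*w22
  w24 <- v3*w23
  w25 <- w24*w6
  w26 <- -q5 + w5
  w27 <- cos(w26)
  w28 <- LSH*w27
  w29 <- mFT*w28
  w30 <- a5*w29
  w31 <- sin(w26)
  w32 <- LSH*w31
  w33 <- mFT*w32
  w34 <- w3*w33
  w35 <- w33*w9
  w36 <- v5^2
  w37 <- cSH*mSH
  w38 <- w27*w37
  w39 <- w31*w37
  w40 <- w3*w39
  w41 <- w39*w9
  w42 <- a3*w29
  w43 <- a4*w29
  w44 <- a3*w38
  w45 <- a4*w38
  w46 <- w15*w32
  w47 <- v5*w46
  w48 <- v4*w14
  w49 <- w32*w48
  w50 <- v5*w49
  w51 <- cSH*w19
  w52 <- w31*w51
  w53 <- v5*w52
  w54 <- v4*w18
  w55 <- cSH*w31
  w56 <- w54*w55
  w57 <- v5*w56
  w58 <- v4*w46
  w59 <- v4*w52
  w60 <- q6 + w26
  w61 <- sin(w60)
  w62 <- fcx*mFT
  w63 <- w61*w62
  w64 <- a3*w63
  w65 <- cos(w60)
  w66 <- fcy*mFT
  w67 <- w65*w66
  w68 <- a3*w67
  w69 <- a4*w63
  w70 <- a4*w67
  w71 <- a6*w63
  w72 <- a6*w67
  w73 <- w62*w65
  w74 <- w3*w73
  w75 <- w73*w9
  w76 <- w36*w73
  w77 <- v6^2
  w78 <- w73*w77
  w79 <- a5*w63
  w80 <- a5*w67
  w81 <- w61*w66
  w82 <- w3*w81
  w83 <- w81*w9
  w84 <- w36*w81
  w85 <- w77*w81
  w86 <- fcx*w15
  w87 <- w65*w86
  w88 <- v5*w87
  w89 <- fcx*w65
  w90 <- w48*w89
  w91 <- v5*w90
  w92 <- w14*w89
  w93 <- v6*w92
  w94 <- v5*w93
  w95 <- fcy*w15
  w96 <- w61*w95
  w97 <- v4*w96
  w98 <- v6*w96
  w99 <- w48*w61
  w100 <- fcy*w99
  w101 <- v6*w100
  w102 <- v4*w87
  w103 <- v6*w87
  w104 <- v6*w90
  w105 <- v5*w61
  w106 <- w105*w95
  w107 <- w105*w48
  w108 <- fcy*w14
  w109 <- w105*w108
  w110 <- v6*w109
  w111 <- fcy*w107 - w101 + w102 + w103 + w104 + w106 + w110 + w64 + w68 + w69 + w70 + w71 + w72 + w74 + w75 + w76 + w78 - w79 - w80 - w82 - w83 - w84 - w85 - w88 - w91 - w94 - w97 - w98
  w112 <- a5*w38 + w111 + w30 + w33*w36 + w34 + w35 + w36*w39 + w40 + w41 - w42 - w43 - w44 - w45 - w47 - w50 - w53 - w57 + w58 + w59
  w113 <- -LTH*a3*mFT*w13 - LTH*a3*mSH*w13 - LTH*a4*mFT*w13 - LTH*a4*mSH*w13 - a3*cTH*mTH*w13 - a4*cTH*mTH*w13 + v4*w25 + w10*w3 + w10*w9 + w112 + w12*w3 + w12*w9 + w17 + w21 + w3*w8 + w8*w9
  w114 <- q3 + q7
  w115 <- sin(w114)
  w116 <- LTH*w115
  w117 <- mFT*w116
  w118 <- v7^2
  w119 <- mSH*w116
  w120 <- w11*w115
  w121 <- cos(w114)
  w122 <- w116*w15
  w123 <- v7*w122
  w124 <- w116*w19
  w125 <- v7*w124
  w126 <- w115*w24
  w127 <- -q8 + w114
  w128 <- cos(w127)
  w129 <- LSH*w128
  w130 <- mFT*w129
  w131 <- a8*w130
  w132 <- sin(w127)
  w133 <- LSH*w132
  w134 <- mFT*w133
  w135 <- w134*w3
  w136 <- w118*w134
  w137 <- v8^2
  w138 <- w128*w37
  w139 <- w132*w37
  w140 <- w139*w3
  w141 <- w118*w139
  w142 <- a3*w130
  w143 <- a7*w130
  w144 <- a3*w138
  w145 <- a7*w138
  w146 <- w133*w15
  w147 <- v8*w146
  w148 <- v7*w14
  w149 <- w133*w148
  w150 <- v8*w149
  w151 <- w132*w51
  w152 <- v8*w151
  w153 <- v7*w18
  w154 <- cSH*w132
  w155 <- w153*w154
  w156 <- v8*w155
  w157 <- v7*w146
  w158 <- v7*w151
  w159 <- q9 + w127
  w160 <- sin(w159)
  w161 <- w160*w62
  w162 <- a3*w161
  w163 <- cos(w159)
  w164 <- w163*w66
  w165 <- a3*w164
  w166 <- a7*w161
  w167 <- a7*w164
  w168 <- a9*w161
  w169 <- a9*w164
  w170 <- w163*w62
  w171 <- w170*w3
  w172 <- w118*w170
  w173 <- w137*w170
  w174 <- v9^2
  w175 <- w170*w174
  w176 <- a8*w161
  w177 <- a8*w164
  w178 <- w160*w66
  w179 <- w178*w3
  w180 <- w118*w178
  w181 <- w137*w178
  w182 <- w174*w178
  w183 <- w163*w86
  w184 <- v8*w183
  w185 <- fcx*w163
  w186 <- w148*w185
  w187 <- v8*w186
  w188 <- w14*w185
  w189 <- v9*w188
  w190 <- v8*w189
  w191 <- w160*w95
  w192 <- v7*w191
  w193 <- v9*w191
  w194 <- w148*w160
  w195 <- fcy*w194
  w196 <- v9*w195
  w197 <- v7*w183
  w198 <- v9*w183
  w199 <- v9*w186
  w200 <- v8*w191
  w201 <- v8*w195
  w202 <- w108*w160
  w203 <- v8*w202
  w204 <- v9*w203
  w205 <- w162 + w165 + w166 + w167 + w168 + w169 + w171 + w172 + w173 + w175 - w176 - w177 - w179 - w180 - w181 - w182 - w184 - w187 - w190 - w192 - w193 - w196 + w197 + w198 + w199 + w200 + w201 + w204
  w206 <- a8*w138 + w131 + w134*w137 + w135 + w136 + w137*w139 + w140 + w141 - w142 - w143 - w144 - w145 - w147 - w150 - w152 - w156 + w157 + w158 + w205
  w207 <- -LTH*a3*mFT*w121 - LTH*a3*mSH*w121 - LTH*a7*mFT*w121 - LTH*a7*mSH*w121 - a3*cTH*mTH*w121 - a7*cTH*mTH*w121 + v7*w126 + w117*w118 + w117*w3 + w118*w119 + w118*w120 + w119*w3 + w120*w3 + w123 + w125 + w206
  w208 <- a3*w2 - cHAT*mHAT*w3*w4 + w113 + w207
  w209 <- a2*mHAT
  w210 <- grav*mHAT
  w211 <- w1*w4
  w212 <- a3*w33
  w213 <- a4*w33
  w214 <- w29*w3
  w215 <- w29*w9
  w216 <- w29*w36
  w217 <- LTH*w13
  w218 <- mFT*w217
  w219 <- w218*w3
  w220 <- w218*w9
  w221 <- mSH*w217
  w222 <- w221*w3
  w223 <- w221*w9
  w224 <- a3*w39
  w225 <- a3*w73
  w226 <- a4*w39
  w227 <- a4*w73
  w228 <- a5*w81
  w229 <- a6*w73
  w230 <- w3*w38
  w231 <- w38*w9
  w232 <- w36*w38
  w233 <- w11*w13
  w234 <- a5*w33
  w235 <- a3*w81
  w236 <- a4*w81
  w237 <- a5*w39
  w238 <- a5*w73
  w239 <- a6*w81
  w240 <- w3*w63
  w241 <- w63*w9
  w242 <- w36*w63
  w243 <- w63*w77
  w244 <- w3*w67
  w245 <- w67*w9
  w246 <- w36*w67
  w247 <- w67*w77
  w248 <- w15*w28
  w249 <- v5*w248
  w250 <- w28*w48
  w251 <- v5*w250
  w252 <- w27*w51
  w253 <- v5*w252
  w254 <- cSH*w27
  w255 <- w254*w54
  w256 <- v5*w255
  w257 <- w61*w86
  w258 <- v4*w257
  w259 <- v6*w61
  w260 <- w259*w86
  w261 <- fcx*w99
  w262 <- v6*w261
  w263 <- w65*w95
  w264 <- v4*w263
  w265 <- v6*w263
  w266 <- fcy*w65
  w267 <- w266*w48
  w268 <- v6*w267
  w269 <- v4*w248
  w270 <- w15*w217
  w271 <- w19*w217
  w272 <- v4*w252
  w273 <- w13*w24
  w274 <- w105*w86
  w275 <- fcx*w107
  w276 <- fcx*w14
  w277 <- w105*w276
  w278 <- v6*w277
  w279 <- v5*w263
  w280 <- v5*w267
  w281 <- w108*w65
  w282 <- v6*w281
  w283 <- v5*w282
  w284 <- a3*w10 + a3*w12 + a3*w8 + a4*w10 + a4*w12 + a4*w8 + v4*w270 + v4*w271 + v4*w273 + w212 + w213 + w214 + w215 + w216 + w219 + w220 + w222 + w223 + w224 + w225 + w226 + w227 + w228 + w229 + w230 + w231 + w232 + w233*w3 + w233*w9 - w234 - w235 - w236 - w237 - w238 - w239 - w240 - w241 - w242 - w243 - w244 - w245 - w246 - w247 - w249 - w251 - w253 - w256 - w258 - w260 - w262 - w264 - w265 - w268 + w269 + w272 + w274 + w275 + w278 + w279 + w280 + w283
  w285 <- a3*w134
  w286 <- a7*w134
  w287 <- w130*w3
  w288 <- w118*w130
  w289 <- w130*w137
  w290 <- LTH*w121
  w291 <- mFT*w290
  w292 <- w291*w3
  w293 <- w118*w291
  w294 <- mSH*w290
  w295 <- w294*w3
  w296 <- w118*w294
  w297 <- a3*w139
  w298 <- a3*w170
  w299 <- a7*w139
  w300 <- a7*w170
  w301 <- a8*w178
  w302 <- a9*w170
  w303 <- w138*w3
  w304 <- w118*w138
  w305 <- w137*w138
  w306 <- w11*w121
  w307 <- a8*w134
  w308 <- a3*w178
  w309 <- a7*w178
  w310 <- a8*w139
  w311 <- a8*w170
  w312 <- a9*w178
  w313 <- w161*w3
  w314 <- w118*w161
  w315 <- w137*w161
  w316 <- w161*w174
  w317 <- w164*w3
  w318 <- w118*w164
  w319 <- w137*w164
  w320 <- w164*w174
  w321 <- w129*w15
  w322 <- v8*w321
  w323 <- w129*w148
  w324 <- v8*w323
  w325 <- w128*w51
  w326 <- v8*w325
  w327 <- cSH*w128
  w328 <- w153*w327
  w329 <- v8*w328
  w330 <- w160*w86
  w331 <- v7*w330
  w332 <- v9*w330
  w333 <- fcx*w194
  w334 <- v9*w333
  w335 <- w163*w95
  w336 <- v7*w335
  w337 <- v9*w335
  w338 <- fcy*w163
  w339 <- w148*w338
  w340 <- v9*w339
  w341 <- v7*w321
  w342 <- w15*w290
  w343 <- w19*w290
  w344 <- v7*w325
  w345 <- w121*w24
  w346 <- v8*w330
  w347 <- v8*w333
  w348 <- v8*w14
  w349 <- v9*w160
  w350 <- fcx*w349
  w351 <- w348*w350
  w352 <- v8*w335
  w353 <- v8*w339
  w354 <- w108*w163
  w355 <- v9*w354
  w356 <- v8*w355
  w357 <- a3*w117 + a3*w119 + a3*w120 + a7*w117 + a7*w119 + a7*w120 + v7*w342 + v7*w343 + v7*w345 + w118*w306 + w285 + w286 + w287 + w288 + w289 + w292 + w293 + w295 + w296 + w297 + w298 + w299 + w3*w306 + w300 + w301 + w302 + w303 + w304 + w305 - w307 - w308 - w309 - w310 - w311 - w312 - w313 - w314 - w315 - w316 - w317 - w318 - w319 - w320 - w322 - w324 - w326 - w329 - w331 - w332 - w334 - w336 - w337 - w340 + w341 + w344 + w346 + w347 + w351 + w352 + w353 + w356
  w358 <- -a3*w211 - w2*w3 + w284 + w357
  w359 <- IFT*a3
  w360 <- ISH*a3
  w361 <- ITH*a3
  w362 <- cHAT^2*mHAT
  w363 <- w0^2*w362
  w364 <- w362*w4^2
  w365 <- a1*cHAT*mHAT
  w366 <- cHAT*w4
  w367 <- hx*w61
  w368 <- hy*w65
  w369 <- tx*w61
  w370 <- ty*w65
  w371 <- hy*w61
  w372 <- ty*w61
  w373 <- hx*w65
  w374 <- tx*w65
  w375 <- w65^2
  w376 <- fcx^2*mFT
  w377 <- w375*w376
  w378 <- w61^2
  w379 <- w376*w378
  w380 <- fcy^2*mFT
  w381 <- w375*w380
  w382 <- w378*w380
  w383 <- IFT*a4 - IFT*a5 + IFT*a6 - a1*w63 - a1*w67 + a2*w73 - a2*w81 + a3*w377 + a3*w379 + a3*w381 + a3*w382 + a4*w377 + a4*w379 + a4*w381 + a4*w382 - a5*w377 - a5*w379 - a5*w381 - a5*w382 + a6*w377 + a6*w379 + a6*w381 + a6*w382 + fx1*w367 + fx1*w368 + fx2*w369 + fx2*w370 + fy1*w371 - fy1*w373 + fy2*w372 - fy2*w374 + grav*w73 - grav*w81
  w384 <- hx*w160
  w385 <- hy*w163
  w386 <- tx*w160
  w387 <- ty*w163
  w388 <- hy*w160
  w389 <- ty*w160
  w390 <- hx*w163
  w391 <- tx*w163
  w392 <- w163^2
  w393 <- w376*w392
  w394 <- w160^2
  w395 <- w376*w394
  w396 <- w380*w392
  w397 <- w380*w394
  w398 <- IFT*a7 - IFT*a8 + IFT*a9 - a1*w161 - a1*w164 + a2*w170 - a2*w178 + a3*w393 + a3*w395 + a3*w396 + a3*w397 + a7*w393 + a7*w395 + a7*w396 + a7*w397 - a8*w393 - a8*w395 - a8*w396 - a8*w397 + a9*w393 + a9*w395 + a9*w396 + a9*w397 + fx3*w384 + fx3*w385 + fx4*w386 + fx4*w387 + fy3*w388 - fy3*w390 + fy4*w389 - fy4*w391 + grav*w170 - grav*w178
  w399 <- w27^2
  w400 <- LSH^2*mFT
  w401 <- w399*w400
  w402 <- w31^2
  w403 <- w400*w402
  w404 <- cSH^2*mSH
  w405 <- w399*w404
  w406 <- w402*w404
  w407 <- fcy*w61
  w408 <- w29*w77
  w409 <- fcx*w61
  w410 <- w29*w409
  w411 <- w266*w29
  w412 <- w276*w61
  w413 <- w28*w412
  w414 <- w28*w281
  w415 <- w108*w61
  w416 <- w32*w415
  w417 <- a5*w32
  w418 <- w32*w92
  w419 <- fcx*w259
  w420 <- w266*w46
  w421 <- w266*w49
  w422 <- ISH*a4 - ISH*a5 + a1*w29 + a1*w38 + a2*w33 + a2*w39 + a3*w401 + a3*w403 + a3*w405 + a3*w406 - a3*w413 - a3*w414 - a3*w416 + a3*w418 + a4*w401 + a4*w403 + a4*w405 + a4*w406 - a4*w413 - a4*w414 - a4*w416 + a4*w418 - a5*w401 - a5*w403 - a5*w405 - a5*w406 + a5*w413 + a5*w414 - a6*w410 - a6*w411 - fx1*w28 - fx2*w28 - fy1*w32 - fy2*w32 + grav*w33 + grav*w39 - v6*w420 - v6*w421 + w101*w28 - w103*w28 - w104*w28 - w110*w28 + w229*w32 - w239*w32 - w243*w32 - w247*w32 + w278*w32 + w28*w94 + w28*w98 + w283*w32 + w407*w408 - w408*w89 + w415*w417 - w417*w92 - w419*w46 - w419*w49
  w423 <- w128^2
  w424 <- w400*w423
  w425 <- w132^2
  w426 <- w400*w425
  w427 <- w404*w423
  w428 <- w404*w425
  w429 <- fcy*w160
  w430 <- w130*w174
  w431 <- fcx*w160
  w432 <- w130*w431
  w433 <- w130*w338
  w434 <- w160*w276
  w435 <- w129*w434
  w436 <- w129*w354
  w437 <- w133*w202
  w438 <- a8*w133
  w439 <- w133*w188
  w440 <- w146*w338
  w441 <- w149*w338
  w442 <- w133*w348
  w443 <- ISH*a7 - ISH*a8 + a1*w130 + a1*w138 + a2*w134 + a2*w139 + a3*w424 + a3*w426 + a3*w427 + a3*w428 - a3*w435 - a3*w436 - a3*w437 + a3*w439 + a7*w424 + a7*w426 + a7*w427 + a7*w428 - a7*w435 - a7*w436 - a7*w437 + a7*w439 - a8*w424 - a8*w426 - a8*w427 - a8*w428 + a8*w435 + a8*w436 - a9*w432 - a9*w433 - fx3*w129 - fx4*w129 - fy3*w133 - fy4*w133 + grav*w134 + grav*w139 - v9*w440 - v9*w441 + w129*w190 + w129*w193 + w129*w196 - w129*w198 - w129*w199 - w129*w204 + w133*w302 - w133*w312 - w133*w316 - w133*w320 + w133*w356 - w146*w350 - w149*w350 - w185*w430 - w188*w438 + w202*w438 + w350*w442 + w429*w430
  w444 <- w13^2
  w445 <- LTH^2
  w446 <- mFT*w445
  w447 <- w444*w446
  w448 <- w6^2
  w449 <- w446*w448
  w450 <- mSH*w445
  w451 <- w444*w450
  w452 <- w448*w450
  w453 <- cTH^2*mTH
  w454 <- w444*w453
  w455 <- w448*w453
  w456 <- w218*w409
  w457 <- w218*w266
  w458 <- w218*w407
  w459 <- w218*w36
  w460 <- w221*w254
  w461 <- w221*w55
  w462 <- w218*w89
  w463 <- w217*w412
  w464 <- w217*w281
  w465 <- w415*w7
  w466 <- w14*w28
  w467 <- w217*w466
  w468 <- w14*w32*w7
  w469 <- w18*w254
  w470 <- w217*w469
  w471 <- w18*w55*w7
  w472 <- w7*w92
  w473 <- w16*w28
  w474 <- w48*w7
  w475 <- w28*w474
  w476 <- w20*w254
  w477 <- w54*w7
  w478 <- w254*w477
  w479 <- w16*w266
  w480 <- w217*w48
  w481 <- fcy*w105
  w482 <- w266*w474
  w483 <- fcx*w105
  w484 <- ITH*a4 + a1*w218 + a1*w221 + a1*w233 + a2*w10 + a2*w12 + a2*w8 + a3*w447 + a3*w449 + a3*w451 + a3*w452 + a3*w454 + a3*w455 - a3*w463 - a3*w464 - a3*w465 + a3*w467 + a3*w468 + a3*w470 + a3*w471 + a3*w472 + a4*w447 + a4*w449 + a4*w451 + a4*w452 + a4*w454 + a4*w455 - a4*w463 - a4*w464 - a4*w465 + a4*w467 + a4*w468 + a4*w470 + a4*w471 + a4*w472 + a5*w456 + a5*w457 - a5*w460 - a6*w456 - a6*w457 - fx1*w217 - fx2*w217 - fy1*w7 - fy2*w7 + grav*w10 + grav*w12 + grav*w8 - v5*w473 - v5*w475 - v5*w476 - v5*w478 + v5*w479 + v5*w482 - v6*w479 - v6*w482 + w101*w217 - w103*w217 - w104*w217 - w106*w217 - w110*w217 - w16*w419 + w16*w483 + w216*w7 - w217*w30 + w217*w47 + w217*w50 + w217*w53 + w217*w57 + w217*w88 + w217*w91 + w217*w94 + w217*w98 + w228*w7 + w229*w7 + w232*w7 - w234*w7 - w237*w7 - w238*w7 - w239*w7 - w242*w7 - w243*w7 - w246*w7 - w247*w7 + w278*w7 + w283*w7 - w32*w459 + w36*w458 - w36*w461 - w419*w474 + w458*w77 - w459*w89 - w462*w77 + w474*w483 - w480*w481
  w485 <- w121^2
  w486 <- w446*w485
  w487 <- w115^2
  w488 <- w446*w487
  w489 <- w450*w485
  w490 <- w450*w487
  w491 <- w453*w485
  w492 <- w453*w487
  w493 <- w291*w431
  w494 <- w291*w338
  w495 <- w291*w429
  w496 <- w137*w291
  w497 <- w294*w327
  w498 <- w154*w294
  w499 <- w185*w291
  w500 <- w290*w434
  w501 <- w290*w354
  w502 <- w116*w202
  w503 <- w129*w14
  w504 <- w290*w503
  w505 <- w116*w133*w14
  w506 <- w18*w327
  w507 <- w290*w506
  w508 <- w116*w154*w18
  w509 <- w116*w188
  w510 <- w122*w129
  w511 <- w116*w148
  w512 <- w129*w511
  w513 <- w124*w327
  w514 <- w116*w153
  w515 <- w327*w514
  w516 <- w122*w338
  w517 <- w338*w511
  w518 <- w122*w431
  w519 <- w431*w511
  w520 <- ITH*a7 + a1*w291 + a1*w294 + a1*w306 + a2*w117 + a2*w119 + a2*w120 + a3*w486 + a3*w488 + a3*w489 + a3*w490 + a3*w491 + a3*w492 - a3*w500 - a3*w501 - a3*w502 + a3*w504 + a3*w505 + a3*w507 + a3*w508 + a3*w509 + a7*w486 + a7*w488 + a7*w489 + a7*w490 + a7*w491 + a7*w492 - a7*w500 - a7*w501 - a7*w502 + a7*w504 + a7*w505 + a7*w507 + a7*w508 + a7*w509 + a8*w493 + a8*w494 - a8*w497 - a9*w493 - a9*w494 - fx3*w290 - fx4*w290 - fy3*w116 - fy4*w116 + grav*w117 + grav*w119 + grav*w120 - v8*w510 - v8*w512 - v8*w513 - v8*w515 + v8*w516 + v8*w517 + v8*w518 + v8*w519 - v9*w516 - v9*w517 + w116*w289 + w116*w301 + w116*w302 + w116*w305 - w116*w307 - w116*w310 - w116*w311 - w116*w312 - w116*w315 - w116*w316 - w116*w319 - w116*w320 + w116*w351 + w116*w356 - w122*w350 - w131*w290 - w133*w496 + w137*w495 - w137*w498 + w147*w290 + w150*w290 + w152*w290 + w156*w290 + w174*w495 - w174*w499 + w184*w290 - w185*w496 + w187*w290 + w190*w290 + w193*w290 + w196*w290 - w198*w290 - w199*w290 - w200*w290 - w201*w290 - w204*w290 - w350*w511
  w521 <- w359 + w383
  w522 <- w360 + w422
  w523 <- a3*w221
  w524 <- a4*w221
  w525 <- a3*w218
  w526 <- a4*w218
  w527 <- w102*w217 + w17*w266 + w17*w409 - w217*w97 - w219*w407 + w219*w89 - w220*w407 + w220*w89 + w225*w7 + w227*w7 - w235*w7 - w236*w7 + w240*w7 + w241*w7 + w244*w7 + w245*w7 - w266*w525 - w266*w526 - w409*w525 - w409*w526 + w521
  w528 <- w359 + w398
  w529 <- w360 + w443
  w530 <- a3*w294
  w531 <- a7*w294
  w532 <- a3*w291
  w533 <- a7*w291
  w534 <- w116*w298 + w116*w300 - w116*w308 - w116*w309 + w116*w313 + w116*w314 + w116*w317 + w116*w318 + w123*w338 + w123*w431 + w185*w292 + w185*w293 - w192*w290 + w197*w290 - w292*w429 - w293*w429 - w338*w532 - w338*w533 - w431*w532 - w431*w533 + w528
  w535 <- -w225 - w227 - w228 - w229 + w235 + w236 + w238 + w239 + w240 + w241 + w242 + w243 + w244 + w245 + w246 + w247 + w258 + w260 + w262 + w264 + w265 + w268 - w274 - w275 - w278 - w279 - w280 - w283
  w536 <- -w298 - w300 - w301 - w302 + w308 + w309 + w311 + w312 + w313 + w314 + w315 + w316 + w317 + w318 + w319 + w320 + w331 + w332 + w334 + w336 + w337 + w340 - w346 - w347 - w351 - w352 - w353 - w356
  w537 <- cHAT*w0
  w538 <- fx1*w373
  w539 <- fx2*w374
  w540 <- fy1*w367
  w541 <- fy1*w368
  w542 <- fy2*w369
  w543 <- fy2*w370
  w544 <- fx1*w371
  w545 <- fx2*w372
  w546 <- a1*w81
  w547 <- a1*w73
  w548 <- a2*w63
  w549 <- a2*w67
  w550 <- grav*w63
  w551 <- grav*w67
  w552 <- -a1*w33 - a1*w39 + a2*w29 + a2*w38 + fx1*w32 + fx2*w32 - fy1*w28 - fy2*w28 + grav*w29 + grav*w38 + w538 + w539 + w540 + w541 + w542 + w543 - w544 - w545 + w546 - w547 - w548 - w549 - w550 - w551
  w553 <- -a1*w10 - a1*w12 - a1*w8 + a2*w218 + a2*w221 + a2*w233 + fx1*w7 + fx2*w7 - fy1*w217 - fy2*w217 + grav*w218 + grav*w221 + grav*w233 + w552
  w554 <- fx3*w390
  w555 <- fx4*w391
  w556 <- fy3*w384
  w557 <- fy3*w385
  w558 <- fy4*w386
  w559 <- fy4*w387
  w560 <- fx3*w388
  w561 <- fx4*w389
  w562 <- a1*w178
  w563 <- a1*w170
  w564 <- a2*w161
  w565 <- a2*w164
  w566 <- grav*w161
  w567 <- grav*w164
  w568 <- -a1*w134 - a1*w139 + a2*w130 + a2*w138 + fx3*w133 + fx4*w133 - fy3*w129 - fy4*w129 + grav*w130 + grav*w138 + w554 + w555 + w556 + w557 + w558 + w559 - w560 - w561 + w562 - w563 - w564 - w565 - w566 - w567
  w569 <- -a1*w117 - a1*w119 - a1*w120 + a2*w291 + a2*w294 + a2*w306 + fx3*w116 + fx4*w116 - fy3*w290 - fy4*w290 + grav*w291 + grav*w294 + grav*w306 + w568
  w570 <- a5*w462
  w571 <- w7*w79
  w572 <- w7*w80
  w573 <- a6*w458
  w574 <- w36*w456
  w575 <- w456*w77
  w576 <- w36*w457
  w577 <- w7*w84
  w578 <- w457*w77
  w579 <- w7*w85
  w580 <- a5*w458
  w581 <- a6*w462
  w582 <- w7*w71
  w583 <- w7*w72
  w584 <- w7*w76
  w585 <- w7*w78
  w586 <- a3*w217*w92
  w587 <- a3*w7
  w588 <- w412*w587
  w589 <- w281*w587
  w590 <- a4*w217*w92
  w591 <- a4*w7
  w592 <- w412*w591
  w593 <- w281*w591
  w594 <- w466*w7
  w595 <- w469*w7
  w596 <- w217*w415
  w597 <- a3*w596
  w598 <- a4*w596
  w599 <- w217*w274
  w600 <- v6*w89
  w601 <- w16*w600
  w602 <- w480*w483
  w603 <- w474*w600
  w604 <- w217*w278
  w605 <- w217*w279
  w606 <- w16*w481
  w607 <- w217*w280
  w608 <- w474*w481
  w609 <- w217*w283
  w610 <- w110*w7
  w611 <- v5*w55
  w612 <- w217*w54
  w613 <- v5*w89
  w614 <- w16*w613
  w615 <- w217*w260
  w616 <- w474*w613
  w617 <- w217*w262
  w618 <- w7*w94
  w619 <- w217*w265
  w620 <- fcy*w259
  w621 <- w16*w620
  w622 <- w217*w268
  w623 <- w474*w620
  w624 <- 2*LSH*LTH*a3*mFT*w13*w31 + 2*LSH*LTH*a4*mFT*w13*w31 + LSH*LTH*a5*mFT*w27*w6 + LSH*LTH*mFT*w13*w27*w36 + LSH*LTH*mFT*w31*w36*w6 + 2*LTH*a3*cSH*mSH*w13*w31 + 2*LTH*a4*cSH*mSH*w13*w31 + LTH*a5*cSH*mSH*w27*w6 + LTH*cSH*mSH*w13*w27*w36 + LTH*cSH*mSH*w31*w36*w6 - a3*w594 - a3*w595 - a4*w594 - a4*w595 - a5*w461 - v5*w254*w612 - w20*w611 - w217*w249 - w217*w251 - w217*w253 - w218*w417 - w47*w7 - w477*w611 - w50*w7 - w552 - w570 - w571 - w572 - w573 - w574 - w575 - w576 - w577 - w578 - w579 + w580 + w581 + w582 + w583 + w584 + w585 + w586 + w588 + w589 + w590 + w592 + w593 - w597 - w598 + w599 + w601 + w602 + w603 + w604 + w605 + w606 + w607 + w608 + w609 + w610 - w614 - w615 - w616 - w617 - w618 - w619 - w621 - w622 - w623
  w625 <- -w538 - w539 - w540 - w541 - w542 - w543 + w544 + w545 - w546 + w547 + w548 + w549 + w550 + w551
  w626 <- a6*w29
  w627 <- w28*w415
  w628 <- w28*w92
  w629 <- a3*w32
  w630 <- a4*w32
  w631 <- -a3*w627 + a3*w628 - a4*w627 + a4*w628 + a5*w627 - a5*w628 + w110*w32 - w260*w28 - w262*w28 - w265*w28 - w268*w28 + w278*w28 + w28*w283 - w281*w417 + w281*w629 + w281*w630 + w32*w71 + w32*w72 + w32*w78 - w32*w85 - w32*w94 - w407*w626 - w410*w77 - w411*w77 - w412*w417 + w412*w629 + w412*w630 + w46*w600 - w46*w620 + w49*w600 - w49*w620 + w626*w89
  w632 <- w570 + w571 + w572 + w573 + w574 + w575 + w576 + w577 + w578 + w579 - w580 - w581 - w582 - w583 - w584 - w585 - w586 - w588 - w589 - w590 - w592 - w593 + w597 + w598 - w599 - w601 - w602 - w603 - w604 - w605 - w606 - w607 - w608 - w609 - w610 + w614 + w615 + w616 + w617 + w618 + w619 + w621 + w622 + w623 - w625 - w631
  w633 <- a8*w499
  w634 <- w116*w176
  w635 <- w116*w177
  w636 <- a9*w495
  w637 <- w137*w493
  w638 <- w174*w493
  w639 <- w137*w494
  w640 <- w116*w181
  w641 <- w174*w494
  w642 <- w116*w182
  w643 <- a8*w495
  w644 <- a9*w499
  w645 <- w116*w168
  w646 <- w116*w169
  w647 <- w116*w173
  w648 <- w116*w175
  w649 <- a3*w188*w290
  w650 <- a3*w116
  w651 <- w434*w650
  w652 <- w354*w650
  w653 <- a7*w188*w290
  w654 <- a7*w116
  w655 <- w434*w654
  w656 <- w354*w654
  w657 <- w116*w503
  w658 <- w116*w506
  w659 <- w202*w290
  w660 <- a3*w659
  w661 <- a7*w659
  w662 <- w290*w346
  w663 <- v9*w185
  w664 <- w122*w663
  w665 <- w290*w347
  w666 <- w511*w663
  w667 <- w290*w351
  w668 <- w290*w352
  w669 <- v8*w429
  w670 <- w122*w669
  w671 <- w290*w353
  w672 <- w511*w669
  w673 <- w290*w356
  w674 <- w116*w204
  w675 <- v8*w154
  w676 <- w153*w290
  w677 <- v8*w185
  w678 <- w122*w677
  w679 <- w290*w332
  w680 <- w511*w677
  w681 <- w290*w334
  w682 <- w116*w190
  w683 <- w290*w337
  w684 <- fcy*w349
  w685 <- w122*w684
  w686 <- w290*w340
  w687 <- w511*w684
  w688 <- 2*LSH*LTH*a3*mFT*w121*w132 + 2*LSH*LTH*a7*mFT*w121*w132 + LSH*LTH*a8*mFT*w115*w128 + LSH*LTH*mFT*w115*w132*w137 + LSH*LTH*mFT*w121*w128*w137 + 2*LTH*a3*cSH*mSH*w121*w132 + 2*LTH*a7*cSH*mSH*w121*w132 + LTH*a8*cSH*mSH*w115*w128 + LTH*cSH*mSH*w115*w132*w137 + LTH*cSH*mSH*w121*w128*w137 - a3*w657 - a3*w658 - a7*w657 - a7*w658 - a8*w498 - v8*w327*w676 - w116*w147 - w116*w150 - w124*w675 - w290*w322 - w290*w324 - w290*w326 - w291*w438 - w514*w675 - w568 - w633 - w634 - w635 - w636 - w637 - w638 - w639 - w640 - w641 - w642 + w643 + w644 + w645 + w646 + w647 + w648 + w649 + w651 + w652 + w653 + w655 + w656 - w660 - w661 + w662 + w664 + w665 + w666 + w667 + w668 + w670 + w671 + w672 + w673 + w674 - w678 - w679 - w680 - w681 - w682 - w683 - w685 - w686 - w687
  w689 <- -w554 - w555 - w556 - w557 - w558 - w559 + w560 + w561 - w562 + w563 + w564 + w565 + w566 + w567
  w690 <- a9*w130
  w691 <- w129*w202
  w692 <- w129*w188
  w693 <- a3*w133
  w694 <- a7*w133
  w695 <- w129*w348
  w696 <- -a3*w691 + a3*w692 - a7*w691 + a7*w692 + a8*w691 - a8*w692 - w129*w332 - w129*w334 - w129*w337 - w129*w340 + w129*w356 + w133*w168 + w133*w169 + w133*w175 - w133*w182 - w133*w190 + w133*w204 + w146*w663 - w146*w684 + w149*w663 - w149*w684 - w174*w432 - w174*w433 + w185*w690 + w350*w695 - w354*w438 + w354*w693 + w354*w694 - w429*w690 - w434*w438 + w434*w693 + w434*w694
  w697 <- w633 + w634 + w635 + w636 + w637 + w638 + w639 + w640 + w641 + w642 - w643 - w644 - w645 - w646 - w647 - w648 - w649 - w651 - w652 - w653 - w655 - w656 + w660 + w661 - w662 - w664 - w665 - w666 - w667 - w668 - w670 - w671 - w672 - w673 - w674 + w678 + w679 + w680 + w681 + w682 + w683 + w685 + w686 + w687 - w689 - w696
  w698 <- -w552
  w699 <- w407*w525
  w700 <- w407*w526
  w701 <- w7*w74
  w702 <- w7*w75
  w703 <- w525*w89
  w704 <- w64*w7
  w705 <- w68*w7
  w706 <- w526*w89
  w707 <- w69*w7
  w708 <- w7*w70
  w709 <- w219*w409
  w710 <- w220*w409
  w711 <- w219*w266
  w712 <- w7*w82
  w713 <- w220*w266
  w714 <- w7*w83
  w715 <- w217*w258
  w716 <- w217*w264
  w717 <- w17*w407
  w718 <- w17*w89
  w719 <- w625 - w699 - w700 - w701 - w702 + w703 + w704 + w705 + w706 + w707 + w708 + w709 + w710 + w711 + w712 + w713 + w714 + w715 + w716 + w717 - w718
  w720 <- -w625
  w721 <- -w568
  w722 <- w429*w532
  w723 <- w429*w533
  w724 <- w116*w171
  w725 <- w116*w172
  w726 <- w185*w532
  w727 <- w116*w162
  w728 <- w116*w165
  w729 <- w185*w533
  w730 <- w116*w166
  w731 <- w116*w167
  w732 <- w292*w431
  w733 <- w293*w431
  w734 <- w292*w338
  w735 <- w116*w179
  w736 <- w293*w338
  w737 <- w116*w180
  w738 <- w290*w331
  w739 <- w290*w336
  w740 <- w123*w429
  w741 <- w123*w185
  w742 <- w689 - w722 - w723 - w724 - w725 + w726 + w727 + w728 + w729 + w730 + w731 + w732 + w733 + w734 + w735 + w736 + w737 + w738 + w739 + w740 - w741
  w743 <- -w689
  w744 <- v4*w23
  w745 <- v5*w14
  w746 <- w32*w745
  w747 <- v5*w18
  w748 <- w55*w747
  w749 <- v5*w92
  w750 <- w108*w259
  w751 <- -w100 + w109 - w749 - w750 + w87 + w90 + w93 - w96
  w752 <- w46 + w49 + w52 + w56 - w746 - w748 + w751
  w753 <- w16 + w20 + w25 + w474 + w477 + w6*w744 + w752
  w754 <- v7*w23
  w755 <- v8*w18
  w756 <- w154*w755
  w757 <- v8*w188
  w758 <- v9*w202
  w759 <- w183 + w186 + w189 - w191 - w195 + w203 - w757 - w758
  w760 <- w146 + w149 + w151 + w155 - w442 - w756 + w759
  w761 <- w115*w754 + w122 + w124 + w126 + w511 + w514 + w760
  w762 <- w28*w745
  w763 <- w254*w747
  w764 <- w259*w276
  w765 <- v5*w281
  w766 <- w13*w744 + w248 + w250 + w252 + w255 - w257 - w261 - w263 - w267 + w270 + w271 + w273 + w277 - w282 + w480 + w612 - w762 - w763 - w764 + w765
  w767 <- w327*w755
  w768 <- w276*w349
  w769 <- w348*w431
  w770 <- v8*w354
  w771 <- w121*w754 + w148*w290 + w321 + w323 + w325 + w328 - w330 - w333 - w335 - w339 + w342 + w343 + w345 - w355 + w676 - w695 - w767 - w768 + w769 + w770
  w772 <- w257 + w261 + w263 + w267 - w277 + w282 + w764 - w765
  w773 <- w330 + w333 + w335 + w339 + w355 + w768 - w769 - w770
  w774 <- w28*w750
  w775 <- w28*w93
  w776 <- w32*w764
  w777 <- w282*w32
  w778 <- -w774 + w775 + w776 + w777
  w779 <- w109*w217 - w217*w749 - w217*w750 + w217*w93 - w277*w7 + w282*w7 + w7*w764 - w7*w765 + w778
  w780 <- -w217*w746 - w217*w748 + w7*w762 + w7*w763 + w779
  w781 <- w129*w758
  w782 <- w129*w189
  w783 <- w133*w768
  w784 <- w133*w355
  w785 <- -w781 + w782 + w783 + w784
  w786 <- w116*w355 + w116*w768 - w116*w769 - w116*w770 + w189*w290 + w203*w290 - w290*w757 - w290*w758 + w785
  w787 <- w116*w695 + w116*w767 - w290*w442 - w290*w756 + w786
  w788 <- -w780
  w789 <- -w100*w217 + w16*w409 + w217*w87 + w217*w90 - w217*w96 + w409*w474 + w479 + w482
  w790 <- w217*w46 + w217*w49 + w217*w52 + w217*w56 - w473 - w475 - w476 - w478 + w789
  w791 <- w780 + w790
  w792 <- -w100*w28 + w109*w28 - w277*w32 - w28*w749 + w28*w87 + w28*w90 - w28*w96 - w32*w765 + w409*w46 + w409*w49 + w420 + w421
  w793 <- w789 + w792
  w794 <- -w779 - w793
  w795 <- -w787
  w796 <- w183*w290 + w186*w290 - w191*w290 - w195*w290 + w516 + w517 + w518 + w519
  w797 <- w146*w290 + w149*w290 + w151*w290 + w155*w290 - w510 - w512 - w513 - w515 + w796
  w798 <- w787 + w797
  w799 <- w129*w183 + w129*w186 - w129*w191 - w129*w195 + w129*w203 - w129*w757 - w133*w770 + w146*w431 + w149*w431 - w431*w442 + w440 + w441
  w800 <- w796 + w799
  w801 <- -w786 - w800
  w802 <- -w774 + w775 + w776 + w777 - w790
  w803 <- -w781 + w782 + w783 + w784 - w797
  w804 <- mHAT + w14 + w18 + w22
  w805 <- w29 + w38 - w63 - w67
  w806 <- w218 + w221 + w233 + w805
  w807 <- w130 + w138 - w161 - w164
  w808 <- w291 + w294 + w306 + w807
  w809 <- -w2 + w806 + w808
  w810 <- -w805
  w811 <- -w63 - w67
  w812 <- -w807
  w813 <- -w161 - w164
  w814 <- w73 - w81
  w815 <- w33 + w39 + w814
  w816 <- w10 + w12 + w8 + w815
  w817 <- w170 - w178
  w818 <- w134 + w139 + w817
  w819 <- w117 + w119 + w120 + w818
  w820 <- -w211 + w816 + w819
  w821 <- -w815
  w822 <- -w818
  w823 <- w377 + w379 + w381 + w382
  w824 <- w393 + w395 + w396 + w397
  w825 <- w401 + w403 + w405 + w406 - w413 - w414 - w416 + w418
  w826 <- w424 + w426 + w427 + w428 - w435 - w436 - w437 + w439
  w827 <- w447 + w449 + w451 + w452 + w454 + w455 - w463 - w464 - w465 + w467 + w468 + w470 + w471 + w472
  w828 <- w486 + w488 + w489 + w490 + w491 + w492 - w500 - w501 - w502 + w504 + w505 + w507 + w508 + w509
  w829 <- IFT + w823
  w830 <- ISH + w825 + w829
  w831 <- ITH + w827 + w830
  w832 <- -w456 - w457 + w7*w73 - w7*w81
  w833 <- -w217*w29 - w33*w7 - w39*w7 - w460 - w830 - w832
  w834 <- w32*w73 - w32*w81 - w410 - w411 + w829
  w835 <- w832 + w834
  w836 <- IFT + w824
  w837 <- ISH + w826 + w836
  w838 <- ITH + w828 + w837
  w839 <- w116*w170 - w116*w178 - w493 - w494
  w840 <- -w116*w134 - w116*w139 - w130*w290 - w497 - w837 - w839
  w841 <- w133*w170 - w133*w178 - w432 - w433 + w836
  w842 <- w839 + w841
  w843 <- -w834
  w844 <- -w841
  w845 <- w217 + w28
  w846 <- w367 + w368 - w845
  w847 <- -w371 + w373
  w848 <- w32 + w847
  w849 <- -w7 - w848
  w850 <- w369 + w370 - w845
  w851 <- -w372 + w374
  w852 <- w32 + w851
  w853 <- -w7 - w852
  w854 <- w129 + w290
  w855 <- w384 + w385 - w854
  w856 <- -w388 + w390
  w857 <- w133 + w856
  w858 <- -w116 - w857
  w859 <- w386 + w387 - w854
  w860 <- -w389 + w391
  w861 <- w133 + w860
  w862 <- -w116 - w861
  w863 <- -w28
  w864 <- w367 + w368
  w865 <- w369 + w370
  w866 <- -w129
  w867 <- w384 + w385
  w868 <- w386 + w387
  out$res[, 1L] <- 2*a1*mFT + a1*mHAT + 2*a1*mSH + 2*a1*mTH - fx1 - fx2 - fx3 - fx4 - w208
  out$res[, 2L] <- a2*w14 + a2*w18 + a2*w22 - fy1 - fy2 - fy3 - fy4 + grav*w14 + grav*w18 + grav*w22 + w209 + w210 + w358
  out$res[, 3L] <- IHAT*a3 + a3*w363 + a3*w364 - w0*w365 - w209*w366 - w210*w366 + 2*w359 + 2*w360 + 2*w361 + w383 + w398 + w422 + w443 + w484 + w520
  out$res[, 4L] <- -tau1 + w361 + w484 + w521 + w522
  out$res[, 5L] <- 2*LSH*LTH*mFT*v3*v4*w27*w6 + LSH*LTH*mFT*w27*w3*w6 + LSH*LTH*mFT*w27*w6*w9 + 2*LTH*cSH*mSH*v3*v4*w27*w6 + LTH*cSH*mSH*w27*w3*w6 + LTH*cSH*mSH*w27*w6*w9 - tau2 - w212*w7 - w213*w7 - w217*w42 - w217*w43 - w217*w58 - w217*w59 - w219*w32 - w220*w32 - w222*w55 - w223*w55 - w224*w7 - w226*w7 - w254*w523 - w254*w524 - w522 - w527
  out$res[, 6L] <- -tau3 + w102*w28 + w106*w28 - w214*w407 + w214*w89 - w215*w407 + w215*w89 - w216*w407 + w216*w89 + w225*w32 + w227*w32 + w228*w32 - w235*w32 - w236*w32 - w238*w32 + w240*w32 + w241*w32 + w242*w32 + w244*w32 + w245*w32 + w246*w32 + w250*w481 + w266*w30 - w266*w42 - w266*w43 - w266*w47 - w266*w50 + w266*w58 - w28*w88 - w28*w91 - w28*w97 + w30*w409 - w409*w42 - w409*w43 + w409*w58 - w46*w483 - w483*w49 + w527
  out$res[, 7L] <- -tau4 + w361 + w520 + w528 + w529
  out$res[, 8L] <- 2*LSH*LTH*mFT*v3*v7*w115*w128 + LSH*LTH*mFT*w115*w118*w128 + LSH*LTH*mFT*w115*w128*w3 + 2*LTH*cSH*mSH*v3*v7*w115*w128 + LTH*cSH*mSH*w115*w118*w128 + LTH*cSH*mSH*w115*w128*w3 - tau5 - w116*w285 - w116*w286 - w116*w297 - w116*w299 - w133*w292 - w133*w293 - w142*w290 - w143*w290 - w154*w295 - w154*w296 - w157*w290 - w158*w290 - w327*w530 - w327*w531 - w529 - w534
  out$res[, 9L] <- -tau6 - w129*w184 - w129*w187 - w129*w192 + w129*w197 + w129*w200 + w129*w201 + w131*w338 + w131*w431 + w133*w298 + w133*w300 + w133*w301 - w133*w308 - w133*w309 - w133*w311 + w133*w313 + w133*w314 + w133*w315 + w133*w317 + w133*w318 + w133*w319 - w142*w338 - w142*w431 - w143*w338 - w143*w431 - w147*w338 - w147*w431 - w150*w338 - w150*w431 + w157*w338 + w157*w431 + w185*w287 + w185*w288 + w185*w289 - w287*w429 - w288*w429 - w289*w429 + w534
  out$Jq[, 1L, 3L] <- -w358
  out$Jq[, 1L, 4L] <- -w284
  out$Jq[, 1L, 5L] <- w212 + w213 + w214 + w215 + w216 + w224 + w226 + w230 + w231 + w232 - w234 - w237 - w249 - w251 - w253 - w256 + w269 + w272 - w535
  out$Jq[, 1L, 6L] <- w535
  out$Jq[, 1L, 7L] <- -w357
  out$Jq[, 1L, 8L] <- w285 + w286 + w287 + w288 + w289 + w297 + w299 + w303 + w304 + w305 - w307 - w310 - w322 - w324 - w326 - w329 + w341 + w344 - w536
  out$Jq[, 1L, 9L] <- w536
  out$Jq[, 2L, 3L] <- -w208
  out$Jq[, 2L, 4L] <- -w113
  out$Jq[, 2L, 5L] <- w112
  out$Jq[, 2L, 6L] <- -w111
  out$Jq[, 2L, 7L] <- -w207
  out$Jq[, 2L, 8L] <- w206
  out$Jq[, 2L, 9L] <- -w205
  out$Jq[, 3L, 3L] <- -w209*w537 - w210*w537 + w365*w4 + w553 + w569
  out$Jq[, 3L, 4L] <- w553
  out$Jq[, 3L, 5L] <- w624
  out$Jq[, 3L, 6L] <- w632
  out$Jq[, 3L, 7L] <- w569
  out$Jq[, 3L, 8L] <- w688
  out$Jq[, 3L, 9L] <- w697
  out$Jq[, 4L, 3L] <- w553
  out$Jq[, 4L, 4L] <- w553
  out$Jq[, 4L, 5L] <- w624
  out$Jq[, 4L, 6L] <- w632
  out$Jq[, 5L, 3L] <- w698
  out$Jq[, 5L, 4L] <- w698
  out$Jq[, 5L, 5L] <- w21*w55 + w214*w217 + w215*w217 + w217*w269 + w217*w272 + w222*w254 + w223*w254 - w32*w525 - w32*w526 + w34*w7 + w35*w7 + w40*w7 + w41*w7 + w42*w7 + w43*w7 + w44*w7 + w45*w7 - w523*w55 - w524*w55 + w552 + w58*w7 + w699 + w700 + w701 + w702 - w703 - w704 - w705 - w706 - w707 - w708 - w709 - w710 - w711 - w712 - w713 - w714 - w715 - w716 - w717 + w718
  out$Jq[, 5L, 6L] <- w631 + w719
  out$Jq[, 6L, 3L] <- w720
  out$Jq[, 6L, 4L] <- w720
  out$Jq[, 6L, 5L] <- w719
  out$Jq[, 6L, 6L] <- LSH*a3*fcy*mFT*w27*w61 + LSH*a4*fcy*mFT*w27*w61 + LSH*a5*fcx*mFT*w27*w65 + LSH*a5*fcx*mFT*w31*w61 + LSH*a5*fcy*mFT*w31*w65 + 2*LSH*fcx*mFT*v3*v4*w31*w65 + 2*LSH*fcx*mFT*v3*v5*w27*w61 + 2*LSH*fcx*mFT*v4*v5*w27*w61 + LSH*fcx*mFT*w3*w31*w65 + LSH*fcx*mFT*w31*w36*w65 + LSH*fcx*mFT*w31*w65*w9 + 2*LSH*fcy*mFT*v3*v5*w27*w65 + 2*LSH*fcy*mFT*v3*v5*w31*w61 + 2*LSH*fcy*mFT*v4*v5*w27*w65 + 2*LSH*fcy*mFT*v4*v5*w31*w61 - w214*w266 - w214*w409 - w215*w266 - w215*w409 - w216*w266 - w216*w409 - w258*w28 - w264*w28 - w30*w407 - w32*w64 - w32*w68 - w32*w69 - w32*w70 - w32*w82 - w32*w83 - w32*w84 - w407*w58 - w42*w89 - w43*w89 - w47*w89 - w50*w89 - w719
  out$Jq[, 7L, 3L] <- w569
  out$Jq[, 7L, 7L] <- w569
  out$Jq[, 7L, 8L] <- w688
  out$Jq[, 7L, 9L] <- w697
  out$Jq[, 8L, 3L] <- w721
  out$Jq[, 8L, 7L] <- w721
  out$Jq[, 8L, 8L] <- w116*w135 + w116*w136 + w116*w140 + w116*w141 + w116*w142 + w116*w143 + w116*w144 + w116*w145 + w116*w157 + w125*w154 - w133*w532 - w133*w533 - w154*w530 - w154*w531 + w287*w290 + w288*w290 + w290*w341 + w290*w344 + w295*w327 + w296*w327 + w568 + w722 + w723 + w724 + w725 - w726 - w727 - w728 - w729 - w730 - w731 - w732 - w733 - w734 - w735 - w736 - w737 - w738 - w739 - w740 + w741
  out$Jq[, 8L, 9L] <- w696 + w742
  out$Jq[, 9L, 3L] <- w743
  out$Jq[, 9L, 7L] <- w743
  out$Jq[, 9L, 8L] <- w742
  out$Jq[, 9L, 9L] <- LSH*a3*fcy*mFT*w128*w160 + LSH*a7*fcy*mFT*w128*w160 + LSH*a8*fcx*mFT*w128*w163 + LSH*a8*fcx*mFT*w132*w160 + LSH*a8*fcy*mFT*w132*w163 + 2*LSH*fcx*mFT*v3*v7*w132*w163 + 2*LSH*fcx*mFT*v3*v8*w128*w160 + 2*LSH*fcx*mFT*v7*v8*w128*w160 + LSH*fcx*mFT*w118*w132*w163 + LSH*fcx*mFT*w132*w137*w163 + LSH*fcx*mFT*w132*w163*w3 + 2*LSH*fcy*mFT*v3*v8*w128*w163 + 2*LSH*fcy*mFT*v3*v8*w132*w160 + 2*LSH*fcy*mFT*v7*v8*w128*w163 + 2*LSH*fcy*mFT*v7*v8*w132*w160 - w129*w331 - w129*w336 - w131*w429 - w133*w162 - w133*w165 - w133*w166 - w133*w167 - w133*w179 - w133*w180 - w133*w181 - w142*w185 - w143*w185 - w147*w185 - w150*w185 - w157*w429 - w287*w338 - w287*w431 - w288*w338 - w288*w431 - w289*w338 - w289*w431 - w742
  out$Jv[, 1L, 3L] <- 2*cHAT*mHAT*v3*w4 - w753 - w761
  out$Jv[, 1L, 4L] <- -w753
  out$Jv[, 1L, 5L] <- w752
  out$Jv[, 1L, 6L] <- -w751
  out$Jv[, 1L, 7L] <- -w761
  out$Jv[, 1L, 8L] <- w760
  out$Jv[, 1L, 9L] <- -w759
  out$Jv[, 2L, 3L] <- -2*v3*w2 + w766 + w771
  out$Jv[, 2L, 4L] <- w766
  out$Jv[, 2L, 5L] <- -w248 - w250 - w252 - w255 + w762 + w763 + w772
  out$Jv[, 2L, 6L] <- -w772
  out$Jv[, 2L, 7L] <- w771
  out$Jv[, 2L, 8L] <- -w321 - w323 - w325 - w328 + w695 + w767 + w773
  out$Jv[, 2L, 9L] <- -w773
  out$Jv[, 3L, 3L] <- -w780 - w787
  out$Jv[, 3L, 4L] <- w788
  out$Jv[, 3L, 5L] <- w791
  out$Jv[, 3L, 6L] <- w794
  out$Jv[, 3L, 7L] <- w795
  out$Jv[, 3L, 8L] <- w798
  out$Jv[, 3L, 9L] <- w801
  out$Jv[, 4L, 3L] <- w788
  out$Jv[, 4L, 4L] <- w788
  out$Jv[, 4L, 5L] <- w791
  out$Jv[, 4L, 6L] <- w794
  out$Jv[, 5L, 3L] <- w802
  out$Jv[, 5L, 4L] <- w802
  out$Jv[, 5L, 5L] <- -w778
  out$Jv[, 5L, 6L] <- w778 + w792
  out$Jv[, 6L, 3L] <- w793
  out$Jv[, 6L, 4L] <- w793
  out$Jv[, 6L, 5L] <- -w792
  out$Jv[, 7L, 3L] <- w795
  out$Jv[, 7L, 7L] <- w795
  out$Jv[, 7L, 8L] <- w798
  out$Jv[, 7L, 9L] <- w801
  out$Jv[, 8L, 3L] <- w803
  out$Jv[, 8L, 7L] <- w803
  out$Jv[, 8L, 8L] <- -w785
  out$Jv[, 8L, 9L] <- w785 + w799
  out$Jv[, 9L, 3L] <- w800
  out$Jv[, 9L, 7L] <- w800
  out$Jv[, 9L, 8L] <- -w799
  out$Ja[, 1L, 1L] <- w804
  out$Ja[, 1L, 3L] <- w809
  out$Ja[, 1L, 4L] <- w806
  out$Ja[, 1L, 5L] <- w810
  out$Ja[, 1L, 6L] <- w811
  out$Ja[, 1L, 7L] <- w808
  out$Ja[, 1L, 8L] <- w812
  out$Ja[, 1L, 9L] <- w813
  out$Ja[, 2L, 2L] <- w804
  out$Ja[, 2L, 3L] <- w820
  out$Ja[, 2L, 4L] <- w816
  out$Ja[, 2L, 5L] <- w821
  out$Ja[, 2L, 6L] <- w814
  out$Ja[, 2L, 7L] <- w819
  out$Ja[, 2L, 8L] <- w822
  out$Ja[, 2L, 9L] <- w817
  out$Ja[, 3L, 1L] <- w809
  out$Ja[, 3L, 2L] <- w820
  out$Ja[, 3L, 3L] <- 2*IFT + IHAT + 2*ISH + 2*ITH + w363 + w364 + w823 + w824 + w825 + w826 + w827 + w828
  out$Ja[, 3L, 4L] <- w831
  out$Ja[, 3L, 5L] <- w833
  out$Ja[, 3L, 6L] <- w835
  out$Ja[, 3L, 7L] <- w838
  out$Ja[, 3L, 8L] <- w840
  out$Ja[, 3L, 9L] <- w842
  out$Ja[, 4L, 1L] <- w806
  out$Ja[, 4L, 2L] <- w816
  out$Ja[, 4L, 3L] <- w831
  out$Ja[, 4L, 4L] <- w831
  out$Ja[, 4L, 5L] <- w833
  out$Ja[, 4L, 6L] <- w835
  out$Ja[, 5L, 1L] <- w810
  out$Ja[, 5L, 2L] <- w821
  out$Ja[, 5L, 3L] <- w833
  out$Ja[, 5L, 4L] <- w833
  out$Ja[, 5L, 5L] <- w830
  out$Ja[, 5L, 6L] <- w843
  out$Ja[, 6L, 1L] <- w811
  out$Ja[, 6L, 2L] <- w814
  out$Ja[, 6L, 3L] <- w835
  out$Ja[, 6L, 4L] <- w835
  out$Ja[, 6L, 5L] <- w843
  out$Ja[, 6L, 6L] <- w829
  out$Ja[, 7L, 1L] <- w808
  out$Ja[, 7L, 2L] <- w819
  out$Ja[, 7L, 3L] <- w838
  out$Ja[, 7L, 7L] <- w838
  out$Ja[, 7L, 8L] <- w840
  out$Ja[, 7L, 9L] <- w842
  out$Ja[, 8L, 1L] <- w812
  out$Ja[, 8L, 2L] <- w822
  out$Ja[, 8L, 3L] <- w840
  out$Ja[, 8L, 7L] <- w840
  out$Ja[, 8L, 8L] <- w837
  out$Ja[, 8L, 9L] <- w844
  out$Ja[, 9L, 1L] <- w813
  out$Ja[, 9L, 2L] <- w817
  out$Ja[, 9L, 3L] <- w842
  out$Ja[, 9L, 7L] <- w842
  out$Ja[, 9L, 8L] <- w844
  out$Ja[, 9L, 9L] <- w836
  out$Jf[, 1L, 1L] <- -1
  out$Jf[, 1L, 3L] <- -1
  out$Jf[, 1L, 5L] <- -1
  out$Jf[, 1L, 7L] <- -1
  out$Jf[, 2L, 2L] <- -1
  out$Jf[, 2L, 4L] <- -1
  out$Jf[, 2L, 6L] <- -1
  out$Jf[, 2L, 8L] <- -1
  out$Jf[, 3L, 1L] <- w846
  out$Jf[, 3L, 2L] <- w849
  out$Jf[, 3L, 3L] <- w850
  out$Jf[, 3L, 4L] <- w853
  out$Jf[, 3L, 5L] <- w855
  out$Jf[, 3L, 6L] <- w858
  out$Jf[, 3L, 7L] <- w859
  out$Jf[, 3L, 8L] <- w862
  out$Jf[, 4L, 1L] <- w846
  out$Jf[, 4L, 2L] <- w849
  out$Jf[, 4L, 3L] <- w850
  out$Jf[, 4L, 4L] <- w853
  out$Jf[, 5L, 1L] <- -w863 - w864
  out$Jf[, 5L, 2L] <- w848
  out$Jf[, 5L, 3L] <- -w863 - w865
  out$Jf[, 5L, 4L] <- w852
  out$Jf[, 6L, 1L] <- w864
  out$Jf[, 6L, 2L] <- -w847
  out$Jf[, 6L, 3L] <- w865
  out$Jf[, 6L, 4L] <- -w851
  out$Jf[, 7L, 5L] <- w855
  out$Jf[, 7L, 6L] <- w858
  out$Jf[, 7L, 7L] <- w859
  out$Jf[, 7L, 8L] <- w862
  out$Jf[, 8L, 5L] <- -w866 - w867
  out$Jf[, 8L, 6L] <- w857
  out$Jf[, 8L, 7L] <- -w866 - w868
  out$Jf[, 8L, 8L] <- w861
  out$Jf[, 9L, 5L] <- w867
  out$Jf[, 9L, 6L] <- -w856
  out$Jf[, 9L, 7L] <- w868
  out$Jf[, 9L, 8L] <- -w860
  out
}

.dyn_cpkin <- function(q, v, p) {
  n <- ncol(q)
  out <- list(px = matrix(0, n, 4L), py = matrix(0, n, 4L),
              vx = matrix(0, n, 4L), vy = matrix(0, n, 4L),
              Jpx = array(0, c(n, 4L, 9L)), Jpy = array(0, c(n, 4L, 9L)),
              Jvx = array(0, c(n, 4L, 9L)), Jvy = array(0, c(n, 4L, 9L)))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- LTH*sin(w0)
  w2 <- -q5 + w0
  w3 <- LSH*sin(w2)
  w4 <- q6 + w2
  w5 <- cos(w4)
  w6 <- sin(w4)
  w7 <- hx*w5 - hy*w6
  w8 <- w3 + w7
  w9 <- w1 + w8
  w10 <- LSH*cos(w2)
  w11 <- -w10
  w12 <- hx*w6
  w13 <- hy*w5
  w14 <- w12 + w13
  w15 <- w11 + w14
  w16 <- LTH*cos(w0)
  w17 <- q2 - w16
  w18 <- w10 + w16
  w19 <- -w12 - w13 + w18
  w20 <- -w14
  w21 <- v6*w20
  w22 <- v3*w19 + v4*w19 + v5*w15 + w21
  w23 <- -w8
  w24 <- v5*w23 + v6*w7
  w25 <- tx*w5 - ty*w6
  w26 <- w25 + w3
  w27 <- w1 + w26
  w28 <- tx*w6
  w29 <- ty*w5
  w30 <- w28 + w29
  w31 <- w11 + w30
  w32 <- w18 - w28 - w29
  w33 <- -w30
  w34 <- v6*w33
  w35 <- v3*w32 + v4*w32 + v5*w31 + w34
  w36 <- -w26
  w37 <- v5*w36 + v6*w25
  w38 <- q3 + q7
  w39 <- LTH*sin(w38)
  w40 <- -q8 + w38
  w41 <- LSH*sin(w40)
  w42 <- q9 + w40
  w43 <- cos(w42)
  w44 <- sin(w42)
  w45 <- hx*w43 - hy*w44
  w46 <- w41 + w45
  w47 <- w39 + w46
  w48 <- LSH*cos(w40)
  w49 <- -w48
  w50 <- hx*w44
  w51 <- hy*w43
  w52 <- w50 + w51
  w53 <- w49 + w52
  w54 <- LTH*cos(w38)
  w55 <- q2 - w54
  w56 <- w48 + w54
  w57 <- -w50 - w51 + w56
  w58 <- -w52
  w59 <- v9*w58
  w60 <- v3*w57 + v7*w57 + v8*w53 + w59
  w61 <- -w46
  w62 <- v8*w61 + v9*w45
  w63 <- tx*w43 - ty*w44
  w64 <- w41 + w63
  w65 <- w39 + w64
  w66 <- tx*w44
  w67 <- ty*w43
  w68 <- w66 + w67
  w69 <- w49 + w68
  w70 <- w56 - w66 - w67
  w71 <- -w68
  w72 <- v9*w71
  w73 <- v3*w70 + v7*w70 + v8*w69 + w72
  w74 <- -w64
  w75 <- v8*w74 + v9*w63
  w76 <- -w9
  w77 <- -w7
  w78 <- v6*w77
  w79 <- v3*w76 + v4*w76 + v5*w8 + w78
  w80 <- -w27
  w81 <- -w25
  w82 <- v6*w81
  w83 <- v3*w80 + v4*w80 + v5*w26 + w82
  w84 <- -w47
  w85 <- -w45
  w86 <- v9*w85
  w87 <- v3*w84 + v7*w84 + v8*w46 + w86
  w88 <- -w65
  w89 <- -w63
  w90 <- v9*w89
  w91 <- v3*w88 + v7*w88 + v8*w64 + w90
  out$px[, 1L] <- q1 + w9
  out$py[, 1L] <- w15 + w17
  out$vx[, 1L] <- v1 + w22
  out$vy[, 1L] <- v2 + v3*w9 + v4*w9 + w24
  out$px[, 2L] <- q1 + w27
  out$py[, 2L] <- w17 + w31
  out$vx[, 2L] <- v1 + w35
  out$vy[, 2L] <- v2 + v3*w27 + v4*w27 + w37
  out$px[, 3L] <- q1 + w47
  out$py[, 3L] <- w53 + w55
  out$vx[, 3L] <- v1 + w60
  out$vy[, 3L] <- v2 + v3*w47 + v7*w47 + w62
  out$px[, 4L] <- q1 + w65
  out$py[, 4L] <- w55 + w69
  out$vx[, 4L] <- v1 + w73
  out$vy[, 4L] <- v2 + v3*w65 + v7*w65 + w75
  out$Jpx[, 1L, 1L] <- 1
  out$Jpy[, 1L, 2L] <- 1
  out$Jpx[, 1L, 3L] <- w19
  out$Jpy[, 1L, 3L] <- w9
  out$Jvx[, 1L, 3L] <- w79
  out$Jvy[, 1L, 3L] <- w22
  out$Jpx[, 1L, 4L] <- w19
  out$Jpy[, 1L, 4L] <- w9
  out$Jvx[, 1L, 4L] <- w79
  out$Jvy[, 1L, 4L] <- w22
  out$Jpx[, 1L, 5L] <- w15
  out$Jpy[, 1L, 5L] <- w23
  out$Jvx[, 1L, 5L] <- v3*w8 + v4*w8 + w24
  out$Jvy[, 1L, 5L] <- v3*w15 + v4*w15 - v5*w15 + v6*w14
  out$Jpx[, 1L, 6L] <- w20
  out$Jpy[, 1L, 6L] <- w7
  out$Jvx[, 1L, 6L] <- v3*w77 + v4*w77 + v5*w7 + w78
  out$Jvy[, 1L, 6L] <- v3*w20 + v4*w20 + v5*w14 + w21
  out$Jpx[, 2L, 1L] <- 1
  out$Jpy[, 2L, 2L] <- 1
  out$Jpx[, 2L, 3L] <- w32
  out$Jpy[, 2L, 3L] <- w27
  out$Jvx[, 2L, 3L] <- w83
  out$Jvy[, 2L, 3L] <- w35
  out$Jpx[, 2L, 4L] <- w32
  out$Jpy[, 2L, 4L] <- w27
  out$Jvx[, 2L, 4L] <- w83
  out$Jvy[, 2L, 4L] <- w35
  out$Jpx[, 2L, 5L] <- w31
  out$Jpy[, 2L, 5L] <- w36
  out$Jvx[, 2L, 5L] <- v3*w26 + v4*w26 + w37
  out$Jvy[, 2L, 5L] <- v3*w31 + v4*w31 - v5*w31 + v6*w30
  out$Jpx[, 2L, 6L] <- w33
  out$Jpy[, 2L, 6L] <- w25
  out$Jvx[, 2L, 6L] <- v3*w81 + v4*w81 + v5*w25 + w82
  out$Jvy[, 2L, 6L] <- v3*w33 + v4*w33 + v5*w30 + w34
  out$Jpx[, 3L, 1L] <- 1
  out$Jpy[, 3L, 2L] <- 1
  out$Jpx[, 3L, 3L] <- w57
  out$Jpy[, 3L, 3L] <- w47
  out$Jvx[, 3L, 3L] <- w87
  out$Jvy[, 3L, 3L] <- w60
  out$Jpx[, 3L, 7L] <- w57
  out$Jpy[, 3L, 7L] <- w47
  out$Jvx[, 3L, 7L] <- w87
  out$Jvy[, 3L, 7L] <- w60
  out$Jpx[, 3L, 8L] <- w53
  out$Jpy[, 3L, 8L] <- w61
  out$Jvx[, 3L, 8L] <- v3*w46 + v7*w46 + w62
  out$Jvy[, 3L, 8L] <- v3*w53 + v7*w53 - v8*w53 + v9*w52
  out$Jpx[, 3L, 9L] <- w58
  out$Jpy[, 3L, 9L] <- w45
  out$Jvx[, 3L, 9L] <- v3*w85 + v7*w85 + v8*w45 + w86
  out$Jvy[, 3L, 9L] <- v3*w58 + v7*w58 + v8*w52 + w59
  out$Jpx[, 4L, 1L] <- 1
  out$Jpy[, 4L, 2L] <- 1
  out$Jpx[, 4L, 3L] <- w70
  out$Jpy[, 4L, 3L] <- w65
  out$Jvx[, 4L, 3L] <- w91
  out$Jvy[, 4L, 3L] <- w73
  out$Jpx[, 4L, 7L] <- w70
  out$Jpy[, 4L, 7L] <- w65
  out$Jvx[, 4L, 7L] <- w91
  out$Jvy[, 4L, 7L] <- w73
  out$Jpx[, 4L, 8L] <- w69
  out$Jpy[, 4L, 8L] <- w74
  out$Jvx[, 4L, 8L] <- v3*w64 + v7*w64 + w75
  out$Jvy[, 4L, 8L] <- v3*w69 + v7*w69 - v8*w69 + v9*w68
  out$Jpx[, 4L, 9L] <- w71
  out$Jpy[, 4L, 9L] <- w63
  out$Jvx[, 4L, 9L] <- v3*w89 + v7*w89 + v8*w63 + w90
  out$Jvy[, 4L, 9L] <- v3*w71 + v7*w71 + v8*w68 + w72
  out
}

.dyn_imu_hat <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- cos(q3)
  w1 <- a1*w0
  w2 <- sin(q3)
  w3 <- a2*w2
  w4 <- grav*w2
  w5 <- w0^2
  w6 <- ry*w5
  w7 <- w2^2
  w8 <- ry*w7
  w9 <- v3^2
  w10 <- rx*w5
  w11 <- rx*w7
  w12 <- -a1*w2 + a2*w0 + grav*w0
  w13 <- 2*v3
  out$ax <- -a3*w6 - a3*w8 + w1 - w10*w9 - w11*w9 + w3 + w4
  out$ay <- a3*w10 + a3*w11 + w12 - w6*w9 - w8*w9
  out$wz <- v3
  out$Jax_a[, 1L] <- w0
  out$Jay_a[, 1L] <- -w2
  out$Jax_a[, 2L] <- w2
  out$Jay_a[, 2L] <- w0
  out$Jax_q[, 3L] <- w12
  out$Jax_v[, 3L] <- -w10*w13 - w11*w13
  out$Jax_a[, 3L] <- -w6 - w8
  out$Jay_q[, 3L] <- -w1 - w3 - w4
  out$Jay_v[, 3L] <- -w13*w6 - w13*w8
  out$Jay_a[, 3L] <- w10 + w11
  out$Jwz_v[, 3L] <- 1
  out
}

.dyn_imu_thigh_r <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- cos(w0)
  w2 <- a1*w1
  w3 <- sin(w0)
  w4 <- a2*w3
  w5 <- grav*w3
  w6 <- w1^2
  w7 <- ry*w6
  w8 <- w3^2
  w9 <- ry*w8
  w10 <- v3^2
  w11 <- rx*w6
  w12 <- rx*w8
  w13 <- v4^2
  w14 <- 2*v3
  w15 <- w11*w14
  w16 <- w12*w14
  w17 <- a1*w3
  w18 <- w14*w7
  w19 <- w14*w9
  w20 <- a2*w1 + grav*w1 - w17
  w21 <- 2*v4
  w22 <- -w11*w21 - w12*w21 - w15 - w16
  w23 <- -w7 - w9
  w24 <- -w2 - w4 - w5
  w25 <- -w18 - w19 - w21*w7 - w21*w9
  w26 <- w11 + w12
  out$ax <- -a3*w7 - a3*w9 - a4*w7 - a4*w9 - v4*w15 - v4*w16 - w10*w11 - w10*w12 - w11*w13 - w12*w13 + w2 + w4 + w5
  out$ay <- a2*w1 + a3*rx*w6 + a3*rx*w8 + a4*rx*w6 + a4*rx*w8 + grav*w1 - v4*w18 - v4*w19 - w10*w7 - w10*w9 - w13*w7 - w13*w9 - w17
  out$wz <- v3 + v4
  out$Jax_a[, 1L] <- w1
  out$Jay_a[, 1L] <- -w3
  out$Jax_a[, 2L] <- w3
  out$Jay_a[, 2L] <- w1
  out$Jax_q[, 3L] <- w20
  out$Jax_v[, 3L] <- w22
  out$Jax_a[, 3L] <- w23
  out$Jay_q[, 3L] <- w24
  out$Jay_v[, 3L] <- w25
  out$Jay_a[, 3L] <- w26
  out$Jwz_v[, 3L] <- 1
  out$Jax_q[, 4L] <- w20
  out$Jax_v[, 4L] <- w22
  out$Jax_a[, 4L] <- w23
  out$Jay_q[, 4L] <- w24
  out$Jay_v[, 4L] <- w25
  out$Jay_a[, 4L] <- w26
  out$Jwz_v[, 4L] <- 1
  out
}

.dyn_imu_shank_r <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- -q5 + w0
  w2 <- cos(w1)
  w3 <- w2^2
  w4 <- ry*w3
  w5 <- sin(w1)
  w6 <- w5^2
  w7 <- ry*w6
  w8 <- v3^2
  w9 <- rx*w3
  w10 <- rx*w6
  w11 <- v4^2
  w12 <- v5^2
  w13 <- 2*v3
  w14 <- w13*w9
  w15 <- w10*w13
  w16 <- 2*v4
  w17 <- w16*w9
  w18 <- w10*w16
  w19 <- cos(w0)
  w20 <- LTH*w2
  w21 <- w19*w20
  w22 <- sin(w0)
  w23 <- LTH*w5
  w24 <- w22*w23
  w25 <- w19*w23
  w26 <- w20*w22
  w27 <- w13*w26
  w28 <- a1*w2 + a2*w5 + grav*w5
  w29 <- a3*w21 + a3*w24 + a4*w21 + a4*w24 + v4*w13*w25 - v4*w27 + w11*w25 - w11*w26 + w25*w8 - w26*w8 + w28
  w30 <- w13*w4
  w31 <- w13*w7
  w32 <- w16*w4
  w33 <- w16*w7
  w34 <- w13*w21
  w35 <- w13*w24
  w36 <- -a1*w5 + a2*w2 + grav*w2
  w37 <- -a3*w25 + a3*w26 - a4*w25 + a4*w26 + v4*w34 + v4*w35 + w11*w21 + w11*w24 + w21*w8 + w24*w8 + w36
  w38 <- 2*v5
  w39 <- -w10*w38 + w14 + w15 + w17 + w18 - w38*w9
  w40 <- 2*LTH*v3*w19*w5 + 2*LTH*v4*w19*w5 - w16*w26 - w27 - w39
  w41 <- w21 + w24 - w4 - w7
  w42 <- -w28
  w43 <- w38*w4
  w44 <- w38*w7
  w45 <- w16*w21 + w16*w24 - w30 - w31 - w32 - w33 + w34 + w35 + w43 + w44
  w46 <- w10 + w9
  w47 <- -w25 + w26 + w46
  out$ax <- -a3*w4 - a3*w7 - a4*w4 - a4*w7 + a5*w4 + a5*w7 - v4*w14 - v4*w15 + v5*w14 + v5*w15 + v5*w17 + v5*w18 - w10*w11 - w10*w12 - w10*w8 - w11*w9 - w12*w9 + w29 - w8*w9
  out$ay <- a3*w10 + a3*w9 + a4*w10 + a4*w9 - a5*w10 - a5*w9 - v4*w30 - v4*w31 + v5*w30 + v5*w31 + v5*w32 + v5*w33 - w11*w4 - w11*w7 - w12*w4 - w12*w7 + w37 - w4*w8 - w7*w8
  out$wz <- v3 + v4 - v5
  out$Jax_a[, 1L] <- w2
  out$Jay_a[, 1L] <- -w5
  out$Jax_a[, 2L] <- w5
  out$Jay_a[, 2L] <- w2
  out$Jax_q[, 3L] <- w36
  out$Jax_v[, 3L] <- w40
  out$Jax_a[, 3L] <- w41
  out$Jay_q[, 3L] <- w42
  out$Jay_v[, 3L] <- w45
  out$Jay_a[, 3L] <- w47
  out$Jwz_v[, 3L] <- 1
  out$Jax_q[, 4L] <- w36
  out$Jax_v[, 4L] <- w40
  out$Jax_a[, 4L] <- w41
  out$Jay_q[, 4L] <- w42
  out$Jay_v[, 4L] <- w45
  out$Jay_a[, 4L] <- w47
  out$Jwz_v[, 4L] <- 1
  out$Jax_q[, 5L] <- -w37
  out$Jax_v[, 5L] <- w39
  out$Jax_a[, 5L] <- w4 + w7
  out$Jay_q[, 5L] <- w29
  out$Jay_v[, 5L] <- w30 + w31 + w32 + w33 - w43 - w44
  out$Jay_a[, 5L] <- -w46
  out$Jwz_v[, 5L] <- -1
  out
}

.dyn_imu_foot_r <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- -q5 + w0
  w2 <- q6 + w1
  w3 <- cos(w2)
  w4 <- a1*w3
  w5 <- sin(w2)
  w6 <- a2*w5
  w7 <- grav*w5
  w8 <- w3^2
  w9 <- ry*w8
  w10 <- w5^2
  w11 <- ry*w10
  w12 <- v3^2
  w13 <- rx*w8
  w14 <- rx*w10
  w15 <- v4^2
  w16 <- v5^2
  w17 <- v6^2
  w18 <- cos(w1)
  w19 <- LSH*w3
  w20 <- w18*w19
  w21 <- a5*w20
  w22 <- sin(w1)
  w23 <- LSH*w5
  w24 <- w22*w23
  w25 <- a5*w24
  w26 <- w19*w22
  w27 <- w12*w26
  w28 <- w15*w26
  w29 <- w16*w26
  w30 <- sin(w0)
  w31 <- LTH*w3
  w32 <- w30*w31
  w33 <- w12*w32
  w34 <- w15*w32
  w35 <- a3*w20
  w36 <- a3*w24
  w37 <- a4*w20
  w38 <- a4*w24
  w39 <- w18*w23
  w40 <- w12*w39
  w41 <- w15*w39
  w42 <- w16*w39
  w43 <- cos(w0)
  w44 <- w31*w43
  w45 <- a3*w44
  w46 <- LTH*w5
  w47 <- w30*w46
  w48 <- a3*w47
  w49 <- a4*w44
  w50 <- a4*w47
  w51 <- w43*w46
  w52 <- w12*w51
  w53 <- w15*w51
  w54 <- 2*v3
  w55 <- w13*w54
  w56 <- w14*w54
  w57 <- 2*v4
  w58 <- w13*w57
  w59 <- w14*w57
  w60 <- w39*w54
  w61 <- v4*w60
  w62 <- w26*w54
  w63 <- v5*w62
  w64 <- w26*w57
  w65 <- v5*w64
  w66 <- v4*w51*w54
  w67 <- v4*w62
  w68 <- v5*w60
  w69 <- w39*w57
  w70 <- v5*w69
  w71 <- w32*w54
  w72 <- v4*w71
  w73 <- w54*w9
  w74 <- w11*w54
  w75 <- w57*w9
  w76 <- w11*w57
  w77 <- 2*v6
  w78 <- w77*w9
  w79 <- w11*w77
  w80 <- w20*w54
  w81 <- w24*w54
  w82 <- w20*w57
  w83 <- w24*w57
  w84 <- w44*w54
  w85 <- w47*w54
  w86 <- -a1*w5 + a2*w3 + grav*w3
  w87 <- a3*w32 - a3*w51 + a4*w32 - a4*w51 + v4*w84 + v4*w85 + w12*w44 + w12*w47 + w15*w44 + w15*w47 + w86
  w88 <- a3*w26 - a3*w39 + a4*w26 - a4*w39 - a5*w26 + a5*w39 + v4*w80 + v4*w81 - v5*w80 - v5*w81 - v5*w82 - v5*w83 + w12*w20 + w12*w24 + w15*w20 + w15*w24 + w16*w20 + w16*w24 + w87
  w89 <- 2*v5
  w90 <- w13*w77 - w13*w89 + w14*w77 - w14*w89 + w55 + w56 + w58 + w59
  w91 <- -w26*w89 + w39*w89 - w60 + w62 + w64 - w69 + w90
  w92 <- 2*LTH*v3*w43*w5 + 2*LTH*v4*w43*w5 - w32*w57 - w71 - w91
  w93 <- -w11 + w20 + w24 - w9
  w94 <- w44 + w47 + w93
  w95 <- w4 + w6 + w7
  w96 <- -w95
  w97 <- w89*w9
  w98 <- w11*w89
  w99 <- w20*w89
  w100 <- w24*w89
  w101 <- -w100 + w44*w57 + w47*w57 - w73 - w74 - w75 - w76 - w78 - w79 + w80 + w81 + w82 + w83 + w84 + w85 + w97 + w98 - w99
  w102 <- w13 + w14
  w103 <- w102 + w26 - w39
  w104 <- w103 + w32 - w51
  w105 <- -w33 - w34 + w45 + w48 + w49 + w50 + w52 + w53 + w66 - w72 + w95
  w106 <- w73 + w74 + w75 + w76 + w78 + w79 - w97 - w98
  out$ax <- -a3*w11 - a3*w9 - a4*w11 - a4*w9 + a5*ry*w10 + a5*ry*w8 - a6*w11 - a6*w9 + 2*rx*v3*v5*w10 + 2*rx*v3*v5*w8 + 2*rx*v4*v5*w10 + 2*rx*v4*v5*w8 + 2*rx*v5*v6*w10 + 2*rx*v5*v6*w8 - v4*w55 - v4*w56 - v6*w55 - v6*w56 - v6*w58 - v6*w59 - w12*w13 - w12*w14 - w13*w15 - w13*w16 - w13*w17 - w14*w15 - w14*w16 - w14*w17 - w21 - w25 - w27 - w28 - w29 - w33 - w34 + w35 + w36 + w37 + w38 + w4 + w40 + w41 + w42 + w45 + w48 + w49 + w50 + w52 + w53 + w6 + w61 + w63 + w65 + w66 - w67 - w68 + w7 - w70 - w72
  out$ay <- a3*w13 + a3*w14 + a4*w13 + a4*w14 - a5*w13 - a5*w14 + a6*w13 + a6*w14 - v4*w73 - v4*w74 + v5*w73 + v5*w74 + v5*w75 + v5*w76 + v5*w78 + v5*w79 - v6*w73 - v6*w74 - v6*w75 - v6*w76 - w11*w12 - w11*w15 - w11*w16 - w11*w17 - w12*w9 - w15*w9 - w16*w9 - w17*w9 + w88
  out$wz <- v3 + v4 - v5 + v6
  out$Jax_a[, 1L] <- w3
  out$Jay_a[, 1L] <- -w5
  out$Jax_a[, 2L] <- w5
  out$Jay_a[, 2L] <- w3
  out$Jax_q[, 3L] <- w86
  out$Jax_v[, 3L] <- w92
  out$Jax_a[, 3L] <- w94
  out$Jay_q[, 3L] <- w96
  out$Jay_v[, 3L] <- w101
  out$Jay_a[, 3L] <- w104
  out$Jwz_v[, 3L] <- 1
  out$Jax_q[, 4L] <- w86
  out$Jax_v[, 4L] <- w92
  out$Jax_a[, 4L] <- w94
  out$Jay_q[, 4L] <- w96
  out$Jay_v[, 4L] <- w101
  out$Jay_a[, 4L] <- w104
  out$Jwz_v[, 4L] <- 1
  out$Jax_q[, 5L] <- -w87
  out$Jax_v[, 5L] <- w91
  out$Jax_a[, 5L] <- -w93
  out$Jay_q[, 5L] <- w105
  out$Jay_v[, 5L] <- w100 + w106 - w80 - w81 - w82 - w83 + w99
  out$Jay_a[, 5L] <- -w103
  out$Jwz_v[, 5L] <- -1
  out$Jax_q[, 6L] <- w88
  out$Jax_v[, 6L] <- -w90
  out$Jax_a[, 6L] <- -w11 - w9
  out$Jay_q[, 6L] <- -w105 + w21 + w25 + w27 + w28 + w29 - w35 - w36 - w37 - w38 - w40 - w41 - w42 - w61 - w63 - w65 + w67 + w68 + w70
  out$Jay_v[, 6L] <- -w106
  out$Jay_a[, 6L] <- w102
  out$Jwz_v[, 6L] <- 1
  out
}

.dyn_imu_thigh_l <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q7
  w1 <- cos(w0)
  w2 <- a1*w1
  w3 <- sin(w0)
  w4 <- a2*w3
  w5 <- grav*w3
  w6 <- w1^2
  w7 <- ry*w6
  w8 <- w3^2
  w9 <- ry*w8
  w10 <- v3^2
  w11 <- rx*w6
  w12 <- rx*w8
  w13 <- v7^2
  w14 <- 2*v3
  w15 <- w11*w14
  w16 <- w12*w14
  w17 <- a1*w3
  w18 <- w14*w7
  w19 <- w14*w9
  w20 <- a2*w1 + grav*w1 - w17
  w21 <- 2*v7
  w22 <- -w11*w21 - w12*w21 - w15 - w16
  w23 <- -w7 - w9
  w24 <- -w2 - w4 - w5
  w25 <- -w18 - w19 - w21*w7 - w21*w9
  w26 <- w11 + w12
  out$ax <- -a3*w7 - a3*w9 - a7*w7 - a7*w9 - v7*w15 - v7*w16 - w10*w11 - w10*w12 - w11*w13 - w12*w13 + w2 + w4 + w5
  out$ay <- a2*w1 + a3*rx*w6 + a3*rx*w8 + a7*rx*w6 + a7*rx*w8 + grav*w1 - v7*w18 - v7*w19 - w10*w7 - w10*w9 - w13*w7 - w13*w9 - w17
  out$wz <- v3 + v7
  out$Jax_a[, 1L] <- w1
  out$Jay_a[, 1L] <- -w3
  out$Jax_a[, 2L] <- w3
  out$Jay_a[, 2L] <- w1
  out$Jax_q[, 3L] <- w20
  out$Jax_v[, 3L] <- w22
  out$Jax_a[, 3L] <- w23
  out$Jay_q[, 3L] <- w24
  out$Jay_v[, 3L] <- w25
  out$Jay_a[, 3L] <- w26
  out$Jwz_v[, 3L] <- 1
  out$Jax_q[, 7L] <- w20
  out$Jax_v[, 7L] <- w22
  out$Jax_a[, 7L] <- w23
  out$Jay_q[, 7L] <- w24
  out$Jay_v[, 7L] <- w25
  out$Jay_a[, 7L] <- w26
  out$Jwz_v[, 7L] <- 1
  out
}

.dyn_imu_shank_l <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q7
  w1 <- -q8 + w0
  w2 <- cos(w1)
  w3 <- w2^2
  w4 <- ry*w3
  w5 <- sin(w1)
  w6 <- w5^2
  w7 <- ry*w6
  w8 <- v3^2
  w9 <- rx*w3
  w10 <- rx*w6
  w11 <- v7^2
  w12 <- v8^2
  w13 <- 2*v3
  w14 <- w13*w9
  w15 <- w10*w13
  w16 <- 2*v7
  w17 <- w16*w9
  w18 <- w10*w16
  w19 <- cos(w0)
  w20 <- LTH*w2
  w21 <- w19*w20
  w22 <- sin(w0)
  w23 <- LTH*w5
  w24 <- w22*w23
  w25 <- w19*w23
  w26 <- w20*w22
  w27 <- w13*w26
  w28 <- a1*w2 + a2*w5 + grav*w5
  w29 <- a3*w21 + a3*w24 + a7*w21 + a7*w24 + v7*w13*w25 - v7*w27 + w11*w25 - w11*w26 + w25*w8 - w26*w8 + w28
  w30 <- w13*w4
  w31 <- w13*w7
  w32 <- w16*w4
  w33 <- w16*w7
  w34 <- w13*w21
  w35 <- w13*w24
  w36 <- -a1*w5 + a2*w2 + grav*w2
  w37 <- -a3*w25 + a3*w26 - a7*w25 + a7*w26 + v7*w34 + v7*w35 + w11*w21 + w11*w24 + w21*w8 + w24*w8 + w36
  w38 <- 2*v8
  w39 <- -w10*w38 + w14 + w15 + w17 + w18 - w38*w9
  w40 <- 2*LTH*v3*w19*w5 + 2*LTH*v7*w19*w5 - w16*w26 - w27 - w39
  w41 <- w21 + w24 - w4 - w7
  w42 <- -w28
  w43 <- w38*w4
  w44 <- w38*w7
  w45 <- w16*w21 + w16*w24 - w30 - w31 - w32 - w33 + w34 + w35 + w43 + w44
  w46 <- w10 + w9
  w47 <- -w25 + w26 + w46
  out$ax <- -a3*w4 - a3*w7 - a7*w4 - a7*w7 + a8*w4 + a8*w7 - v7*w14 - v7*w15 + v8*w14 + v8*w15 + v8*w17 + v8*w18 - w10*w11 - w10*w12 - w10*w8 - w11*w9 - w12*w9 + w29 - w8*w9
  out$ay <- a3*w10 + a3*w9 + a7*w10 + a7*w9 - a8*w10 - a8*w9 - v7*w30 - v7*w31 + v8*w30 + v8*w31 + v8*w32 + v8*w33 - w11*w4 - w11*w7 - w12*w4 - w12*w7 + w37 - w4*w8 - w7*w8
  out$wz <- v3 + v7 - v8
  out$Jax_a[, 1L] <- w2
  out$Jay_a[, 1L] <- -w5
  out$Jax_a[, 2L] <- w5
  out$Jay_a[, 2L] <- w2
  out$Jax_q[, 3L] <- w36
  out$Jax_v[, 3L] <- w40
  out$Jax_a[, 3L] <- w41
  out$Jay_q[, 3L] <- w42
  out$Jay_v[, 3L] <- w45
  out$Jay_a[, 3L] <- w47
  out$Jwz_v[, 3L] <- 1
  out$Jax_q[, 7L] <- w36
  out$Jax_v[, 7L] <- w40
  out$Jax_a[, 7L] <- w41
  out$Jay_q[, 7L] <- w42
  out$Jay_v[, 7L] <- w45
  out$Jay_a[, 7L] <- w47
  out$Jwz_v[, 7L] <- 1
  out$Jax_q[, 8L] <- -w37
  out$Jax_v[, 8L] <- w39
  out$Jax_a[, 8L] <- w4 + w7
  out$Jay_q[, 8L] <- w29
  out$Jay_v[, 8L] <- w30 + w31 + w32 + w33 - w43 - w44
  out$Jay_a[, 8L] <- -w46
  out$Jwz_v[, 8L] <- -1
  out
}

.dyn_imu_foot_l <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  z <- matrix(0, n, 9L)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),
              Jax_q = z, Jax_v = z, Jax_a = z,
              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q7
  w1 <- -q8 + w0
  w2 <- q9 + w1
  w3 <- cos(w2)
  w4 <- a1*w3
  w5 <- sin(w2)
  w6 <- a2*w5
  w7 <- grav*w5
  w8 <- w3^2
  w9 <- ry*w8
  w10 <- w5^2
  w11 <- ry*w10
  w12 <- v3^2
  w13 <- rx*w8
  w14 <- rx*w10
  w15 <- v7^2
  w16 <- v8^2
  w17 <- v9^2
  w18 <- cos(w1)
  w19 <- LSH*w3
  w20 <- w18*w19
  w21 <- a8*w20
  w22 <- sin(w1)
  w23 <- LSH*w5
  w24 <- w22*w23
  w25 <- a8*w24
  w26 <- w19*w22
  w27 <- w12*w26
  w28 <- w15*w26
  w29 <- w16*w26
  w30 <- sin(w0)
  w31 <- LTH*w3
  w32 <- w30*w31
  w33 <- w12*w32
  w34 <- w15*w32
  w35 <- a3*w20
  w36 <- a3*w24
  w37 <- a7*w20
  w38 <- a7*w24
  w39 <- w18*w23
  w40 <- w12*w39
  w41 <- w15*w39
  w42 <- w16*w39
  w43 <- cos(w0)
  w44 <- w31*w43
  w45 <- a3*w44
  w46 <- LTH*w5
  w47 <- w30*w46
  w48 <- a3*w47
  w49 <- a7*w44
  w50 <- a7*w47
  w51 <- w43*w46
  w52 <- w12*w51
  w53 <- w15*w51
  w54 <- 2*v3
  w55 <- w13*w54
  w56 <- w14*w54
  w57 <- 2*v7
  w58 <- w13*w57
  w59 <- w14*w57
  w60 <- w39*w54
  w61 <- v7*w60
  w62 <- w26*w54
  w63 <- v8*w62
  w64 <- w26*w57
  w65 <- v8*w64
  w66 <- v7*w51*w54
  w67 <- v7*w62
  w68 <- v8*w60
  w69 <- w39*w57
  w70 <- v8*w69
  w71 <- w32*w54
  w72 <- v7*w71
  w73 <- w54*w9
  w74 <- w11*w54
  w75 <- w57*w9
  w76 <- w11*w57
  w77 <- 2*v9
  w78 <- w77*w9
  w79 <- w11*w77
  w80 <- w20*w54
  w81 <- w24*w54
  w82 <- w20*w57
  w83 <- w24*w57
  w84 <- w44*w54
  w85 <- w47*w54
  w86 <- -a1*w5 + a2*w3 + grav*w3
  w87 <- a3*w32 - a3*w51 + a7*w32 - a7*w51 + v7*w84 + v7*w85 + w12*w44 + w12*w47 + w15*w44 + w15*w47 + w86
  w88 <- a3*w26 - a3*w39 + a7*w26 - a7*w39 - a8*w26 + a8*w39 + v7*w80 + v7*w81 - v8*w80 - v8*w81 - v8*w82 - v8*w83 + w12*w20 + w12*w24 + w15*w20 + w15*w24 + w16*w20 + w16*w24 + w87
  w89 <- 2*v8
  w90 <- w13*w77 - w13*w89 + w14*w77 - w14*w89 + w55 + w56 + w58 + w59
  w91 <- -w26*w89 + w39*w89 - w60 + w62 + w64 - w69 + w90
  w92 <- 2*LTH*v3*w43*w5 + 2*LTH*v7*w43*w5 - w32*w57 - w71 - w91
  w93 <- -w11 + w20 + w24 - w9
  w94 <- w44 + w47 + w93
  w95 <- w4 + w6 + w7
  w96 <- -w95
  w97 <- w89*w9
  w98 <- w11*w89
  w99 <- w20*w89
  w100 <- w24*w89
  w101 <- -w100 + w44*w57 + w47*w57 - w73 - w74 - w75 - w76 - w78 - w79 + w80 + w81 + w82 + w83 + w84 + w85 + w97 + w98 - w99
  w102 <- w13 + w14
  w103 <- w102 + w26 - w39
  w104 <- w103 + w32 - w51
  w105 <- -w33 - w34 + w45 + w48 + w49 + w50 + w52 + w53 + w66 - w72 + w95
  w106 <- w73 + w74 + w75 + w76 + w78 + w79 - w97 - w98
  out$ax <- -a3*w11 - a3*w9 - a7*w11 - a7*w9 + a8*ry*w10 + a8*ry*w8 - a9*w11 - a9*w9 + 2*rx*v3*v8*w10 + 2*rx*v3*v8*w8 + 2*rx*v7*v8*w10 + 2*rx*v7*v8*w8 + 2*rx*v8*v9*w10 + 2*rx*v8*v9*w8 - v7*w55 - v7*w56 - v9*w55 - v9*w56 - v9*w58 - v9*w59 - w12*w13 - w12*w14 - w13*w15 - w13*w16 - w13*w17 - w14*w15 - w14*w16 - w14*w17 - w21 - w25 - w27 - w28 - w29 - w33 - w34 + w35 + w36 + w37 + w38 + w4 + w40 + w41 + w42 + w45 + w48 + w49 + w50 + w52 + w53 + w6 + w61 + w63 + w65 + w66 - w67 - w68 + w7 - w70 - w72
  out$ay <- a3*w13 + a3*w14 + a7*w13 + a7*w14 - a8*w13 - a8*w14 + a9*w13 + a9*w14 - v7*w73 - v7*w74 + v8*w73 + v8*w74 + v8*w75 + v8*w76 + v8*w78 + v8*w79 - v9*w73 - v9*w74 - v9*w75 - v9*w76 - w11*w12 - w11*w15 - w11*w16 - w11*w17 - w12*w9 - w15*w9 - w16*w9 - w17*w9 + w88
  out$wz <- v3 + v7 - v8 + v9
  out$Jax_a[, 1L] <- w3
  out$Jay_a[, 1L] <- -w5
  out$Jax_a[, 2L] <- w5
  out$Jay_a[, 2L] <- w3
  out$Jax_q[, 3L] <- w86
  out$Jax_v[, 3L] <- w92
  out$Jax_a[, 3L] <- w94
  out$Jay_q[, 3L] <- w96
  out$Jay_v[, 3L] <- w101
  out$Jay_a[, 3L] <- w104
  out$Jwz_v[, 3L] <- 1
  out$Jax_q[, 7L] <- w86
  out$Jax_v[, 7L] <- w92
  out$Jax_a[, 7L] <- w94
  out$Jay_q[, 7L] <- w96
  out$Jay_v[, 7L] <- w101
  out$Jay_a[, 7L] <- w104
  out$Jwz_v[, 7L] <- 1
  out$Jax_q[, 8L] <- -w87
  out$Jax_v[, 8L] <- w91
  out$Jax_a[, 8L] <- -w93
  out$Jay_q[, 8L] <- w105
  out$Jay_v[, 8L] <- w100 + w106 - w80 - w81 - w82 - w83 + w99
  out$Jay_a[, 8L] <- -w103
  out$Jwz_v[, 8L] <- -1
  out$Jax_q[, 9L] <- w88
  out$Jax_v[, 9L] <- -w90
  out$Jax_a[, 9L] <- -w11 - w9
  out$Jay_q[, 9L] <- -w105 + w21 + w25 + w27 + w28 + w29 - w35 - w36 - w37 - w38 - w40 - w41 - w42 - w61 - w63 - w65 + w67 + w68 + w70
  out$Jay_v[, 9L] <- -w106
  out$Jay_a[, 9L] <- w102
  out$Jwz_v[, 9L] <- 1
  out
}

.dyn_imu_fns <- list(hat = .dyn_imu_hat, thigh_r = .dyn_imu_thigh_r, shank_r = .dyn_imu_shank_r, foot_r = .dyn_imu_foot_r, thigh_l = .dyn_imu_thigh_l, shank_l = .dyn_imu_shank_l, foot_l = .dyn_imu_foot_l)

.dyn_eom_val <- function(q, v, a, tau, f, p) {
  n <- ncol(q)
  out <- list(res = matrix(0, n, 9L))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  tau1 <- tau[1L, ]
  tau2 <- tau[2L, ]
  tau3 <- tau[3L, ]
  tau4 <- tau[4L, ]
  tau5 <- tau[5L, ]
  tau6 <- tau[6L, ]
  fx1 <- f[1L, ]
  fy1 <- f[2L, ]
  fx2 <- f[3L, ]
  fy2 <- f[4L, ]
  fx3 <- f[5L, ]
  fy3 <- f[6L, ]
  fx4 <- f[7L, ]
  fy4 <- f[8L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- -q5 + w0
  w2 <- cos(w1)
  w3 <- LSH*w2
  w4 <- a5*mFT
  w5 <- w3*w4
  w6 <- q3 + q7
  w7 <- -q8 + w6
  w8 <- cos(w7)
  w9 <- LSH*w8
  w10 <- a8*mFT
  w11 <- w10*w9
  w12 <- sin(w1)
  w13 <- LSH*w12
  w14 <- v3^2
  w15 <- mFT*w14
  w16 <- w13*w15
  w17 <- sin(w7)
  w18 <- LSH*w17
  w19 <- w15*w18
  w20 <- v4^2
  w21 <- mFT*w13
  w22 <- w20*w21
  w23 <- v5^2
  w24 <- w21*w23
  w25 <- v7^2
  w26 <- mFT*w18
  w27 <- w25*w26
  w28 <- v8^2
  w29 <- w26*w28
  w30 <- sin(w0)
  w31 <- LTH*w30
  w32 <- w15*w31
  w33 <- sin(w6)
  w34 <- LTH*w33
  w35 <- w15*w34
  w36 <- w20*w31
  w37 <- mFT*w36
  w38 <- w25*w34
  w39 <- mFT*w38
  w40 <- mSH*w14
  w41 <- cos(q3)
  w42 <- cHAT*mHAT
  w43 <- w41*w42
  w44 <- a3*mFT
  w45 <- q6 + w1
  w46 <- sin(w45)
  w47 <- fcx*w46
  w48 <- q9 + w7
  w49 <- sin(w48)
  w50 <- fcx*w49
  w51 <- cos(w45)
  w52 <- fcy*w51
  w53 <- cos(w48)
  w54 <- fcy*w53
  w55 <- a4*mFT
  w56 <- cSH*w2
  w57 <- mSH*w56
  w58 <- a5*w57
  w59 <- a6*mFT
  w60 <- w47*w59
  w61 <- w52*w59
  w62 <- a7*mFT
  w63 <- cSH*w8
  w64 <- mSH*w63
  w65 <- a8*w64
  w66 <- a9*mFT
  w67 <- w50*w66
  w68 <- w54*w66
  w69 <- cSH*w40
  w70 <- w12*w69
  w71 <- w17*w69
  w72 <- cSH*mSH
  w73 <- w12*w72
  w74 <- w20*w73
  w75 <- w23*w73
  w76 <- w17*w72
  w77 <- w25*w76
  w78 <- w28*w76
  w79 <- cTH*mTH
  w80 <- w14*w79
  w81 <- w20*w79
  w82 <- w25*w79
  w83 <- fcx*w15
  w84 <- w51*w83
  w85 <- w53*w83
  w86 <- fcx*mFT
  w87 <- w51*w86
  w88 <- w20*w87
  w89 <- w23*w87
  w90 <- v6^2
  w91 <- w87*w90
  w92 <- w53*w86
  w93 <- w25*w92
  w94 <- w28*w92
  w95 <- v9^2
  w96 <- w92*w95
  w97 <- cos(w0)
  w98 <- cos(w6)
  w99 <- sin(q3)
  w100 <- 2*v3
  w101 <- v4*w100
  w102 <- w101*w21
  w103 <- v7*w100
  w104 <- w103*w26
  w105 <- w101*w31
  w106 <- w103*w34
  w107 <- w101*w73
  w108 <- w103*w76
  w109 <- w101*w79
  w110 <- w103*w79
  w111 <- w101*w87
  w112 <- v6*w87
  w113 <- w100*w112
  w114 <- w103*w92
  w115 <- v9*w92
  w116 <- w100*w115
  w117 <- 2*v4
  w118 <- w112*w117
  w119 <- 2*v7
  w120 <- w115*w119
  w121 <- fcy*mFT
  w122 <- w121*w46
  w123 <- v5*w122
  w124 <- w100*w123
  w125 <- w121*w49
  w126 <- v8*w125
  w127 <- w100*w126
  w128 <- w117*w123
  w129 <- 2*v6
  w130 <- w123*w129
  w131 <- w119*w126
  w132 <- 2*v9
  w133 <- w126*w132
  w134 <- a2*mHAT
  w135 <- grav*mHAT
  w136 <- 2*a2
  w137 <- 2*grav
  w138 <- w13*w44
  w139 <- w18*w44
  w140 <- w13*w55
  w141 <- w18*w62
  w142 <- mFT*w3
  w143 <- w142*w23
  w144 <- mFT*w9
  w145 <- w144*w28
  w146 <- w31*w44
  w147 <- w34*w44
  w148 <- a3*mSH
  w149 <- w31*w55
  w150 <- a4*mSH
  w151 <- w150*w31
  w152 <- w34*w62
  w153 <- a7*mSH
  w154 <- w153*w34
  w155 <- LTH*w97
  w156 <- LTH*w98
  w157 <- w155*w20
  w158 <- w156*w25
  w159 <- cSH*w148
  w160 <- w12*w159
  w161 <- w159*w17
  w162 <- a3*w79
  w163 <- fcx*w44
  w164 <- cSH*w12
  w165 <- fcx*w51
  w166 <- fcy*w46
  w167 <- w166*w4
  w168 <- w165*w59
  w169 <- cSH*w17
  w170 <- fcx*w53
  w171 <- fcy*w49
  w172 <- w10*w171
  w173 <- w170*w66
  w174 <- w23*w57
  w175 <- w28*w64
  w176 <- w13*w4
  w177 <- w10*w18
  w178 <- a5*w73
  w179 <- w165*w4
  w180 <- a6*w122
  w181 <- a8*w76
  w182 <- w10*w170
  w183 <- a9*w125
  w184 <- mFT*w47
  w185 <- w184*w23
  w186 <- w184*w90
  w187 <- mFT*w50
  w188 <- w187*w28
  w189 <- w187*w95
  w190 <- mFT*w52
  w191 <- w190*w23
  w192 <- w190*w90
  w193 <- mFT*w54
  w194 <- w193*w28
  w195 <- w193*w95
  w196 <- v5*w142
  w197 <- w100*w196
  w198 <- v8*w144
  w199 <- w100*w198
  w200 <- w117*w196
  w201 <- w119*w198
  w202 <- v5*w57
  w203 <- w100*w202
  w204 <- v8*w64
  w205 <- w100*w204
  w206 <- w117*w202
  w207 <- w119*w204
  w208 <- v6*w184
  w209 <- w100*w208
  w210 <- v9*w187
  w211 <- w100*w210
  w212 <- w117*w208
  w213 <- w119*w210
  w214 <- v6*w190
  w215 <- w100*w214
  w216 <- v9*w193
  w217 <- w100*w216
  w218 <- w117*w214
  w219 <- w119*w216
  w220 <- w101*w155
  w221 <- w103*w156
  w222 <- v5*w184
  w223 <- w100*w222
  w224 <- v8*w187
  w225 <- w100*w224
  w226 <- w117*w222
  w227 <- w129*w222
  w228 <- w119*w224
  w229 <- w132*w224
  w230 <- v5*w190
  w231 <- w100*w230
  w232 <- v8*w193
  w233 <- w100*w232
  w234 <- w117*w230
  w235 <- w129*w230
  w236 <- w119*w232
  w237 <- w132*w232
  w238 <- IFT*a3
  w239 <- ISH*a3
  w240 <- ITH*a3
  w241 <- a3*cHAT^2*mHAT
  w242 <- cHAT*w99
  w243 <- w51^2
  w244 <- fcx^2
  w245 <- w244*w44
  w246 <- w46^2
  w247 <- fcy^2
  w248 <- w247*w44
  w249 <- w244*w55
  w250 <- w247*w55
  w251 <- w244*w59
  w252 <- w247*w59
  w253 <- w244*w4
  w254 <- w247*w4
  w255 <- IFT*a4 - IFT*a5 + IFT*a6 - a1*w184 - a1*w190 - a2*w122 + a2*w87 + fx1*hx*w46 + fx1*hy*w51 + fx2*tx*w46 + fx2*ty*w51 - fy1*hx*w51 + fy1*hy*w46 - fy2*tx*w51 + fy2*ty*w46 - grav*w122 + grav*w87 + w243*w245 + w243*w248 + w243*w249 + w243*w250 + w243*w251 + w243*w252 - w243*w253 - w243*w254 + w245*w246 + w246*w248 + w246*w249 + w246*w250 + w246*w251 + w246*w252 - w246*w253 - w246*w254
  w256 <- w53^2
  w257 <- w49^2
  w258 <- w244*w62
  w259 <- w247*w62
  w260 <- w244*w66
  w261 <- w247*w66
  w262 <- w10*w244
  w263 <- w10*w247
  w264 <- IFT*a7 - IFT*a8 + IFT*a9 - a1*w187 - a1*w193 - a2*w125 + a2*w92 + fx3*hx*w49 + fx3*hy*w53 + fx4*tx*w49 + fx4*ty*w53 - fy3*hx*w53 + fy3*hy*w49 - fy4*tx*w53 + fy4*ty*w49 - grav*w125 + grav*w92 + w245*w256 + w245*w257 + w248*w256 + w248*w257 + w256*w258 + w256*w259 + w256*w260 + w256*w261 - w256*w262 - w256*w263 + w257*w258 + w257*w259 + w257*w260 + w257*w261 - w257*w262 - w257*w263
  w265 <- w2^2
  w266 <- LSH^2
  w267 <- w266*w44
  w268 <- w12^2
  w269 <- cSH^2
  w270 <- w148*w269
  w271 <- w266*w55
  w272 <- w150*w269
  w273 <- w266*w4
  w274 <- mSH*w269
  w275 <- a5*w274
  w276 <- w122*w90
  w277 <- w21*w90
  w278 <- w3*w44
  w279 <- w278*w47
  w280 <- w278*w52
  w281 <- w138*w166
  w282 <- w3*w55
  w283 <- w282*w47
  w284 <- w282*w52
  w285 <- w140*w166
  w286 <- w165*w176
  w287 <- w138*w165
  w288 <- w140*w165
  w289 <- w4*w47
  w290 <- w289*w3
  w291 <- w4*w52
  w292 <- w291*w3
  w293 <- w13*w167
  w294 <- v6*w21
  w295 <- w294*w47
  w296 <- w294*w52
  w297 <- 2*v5*w112
  w298 <- v5*w21
  w299 <- w129*w298
  w300 <- v6*w122
  w301 <- w100*w300
  w302 <- w117*w300
  w303 <- ISH*a4 - ISH*a5 + a1*w142 + a1*w57 + a2*w21 + a2*w73 + a6*w165*w21 - fx1*w3 - fx2*w3 - fy1*w13 - fy2*w13 + grav*w21 + grav*w73 - w100*w295 - w100*w296 - w113*w3 - w117*w295 - w117*w296 - w118*w3 - w13*w180 - w130*w3 + w265*w267 + w265*w270 + w265*w271 + w265*w272 - w265*w273 - w265*w275 + w267*w268 + w268*w270 + w268*w271 + w268*w272 - w268*w273 - w268*w275 + w276*w3 - w277*w47 - w277*w52 - 2*w279 - 2*w280 - 2*w281 - 2*w283 - 2*w284 - 2*w285 - 2*w286 + 2*w287 + 2*w288 + 2*w290 + 2*w292 + 2*w293 + w297*w3 + w299*w47 + w299*w52 + w3*w301 + w3*w302 - w3*w60 - w3*w61 - w3*w91
  w304 <- w8^2
  w305 <- w17^2
  w306 <- w266*w62
  w307 <- w153*w269
  w308 <- w10*w266
  w309 <- a8*w274
  w310 <- w125*w95
  w311 <- w26*w95
  w312 <- w44*w9
  w313 <- w312*w50
  w314 <- w312*w54
  w315 <- w139*w171
  w316 <- w62*w9
  w317 <- w316*w50
  w318 <- w316*w54
  w319 <- w141*w171
  w320 <- w170*w177
  w321 <- w139*w170
  w322 <- w141*w170
  w323 <- w10*w50
  w324 <- w323*w9
  w325 <- w10*w54
  w326 <- w325*w9
  w327 <- w172*w18
  w328 <- v9*w26
  w329 <- w328*w50
  w330 <- w328*w54
  w331 <- 2*v8*w115
  w332 <- v8*w26
  w333 <- w132*w332
  w334 <- v9*w125
  w335 <- w100*w334
  w336 <- w119*w334
  w337 <- ISH*a7 - ISH*a8 + a1*w144 + a1*w64 + a2*w26 + a2*w76 + a9*w170*w26 - fx3*w9 - fx4*w9 - fy3*w18 - fy4*w18 + grav*w26 + grav*w76 - w100*w329 - w100*w330 - w116*w9 - w119*w329 - w119*w330 - w120*w9 - w133*w9 - w18*w183 + w267*w304 + w267*w305 + w270*w304 + w270*w305 + w304*w306 + w304*w307 - w304*w308 - w304*w309 + w305*w306 + w305*w307 - w305*w308 - w305*w309 + w310*w9 - w311*w50 - w311*w54 - 2*w313 - 2*w314 - 2*w315 - 2*w317 - 2*w318 - 2*w319 - 2*w320 + 2*w321 + 2*w322 + 2*w324 + 2*w326 + 2*w327 + w331*w9 + w333*w50 + w333*w54 + w335*w9 + w336*w9 - w67*w9 - w68*w9 - w9*w96
  w338 <- a1*mFT
  w339 <- a1*mSH
  w340 <- a2*mFT
  w341 <- a2*mSH
  w342 <- grav*mFT
  w343 <- grav*mSH
  w344 <- a1*w79
  w345 <- a2*w79
  w346 <- w97^2
  w347 <- LTH^2
  w348 <- w347*w44
  w349 <- w30^2
  w350 <- w148*w347
  w351 <- cTH^2*mTH
  w352 <- a3*w351
  w353 <- w347*w55
  w354 <- w150*w347
  w355 <- a4*w351
  w356 <- grav*w79
  w357 <- w122*w23
  w358 <- w155*w44
  w359 <- w358*w47
  w360 <- w358*w52
  w361 <- w146*w166
  w362 <- w155*w55
  w363 <- w362*w47
  w364 <- w362*w52
  w365 <- w149*w166
  w366 <- w155*w278
  w367 <- w138*w31
  w368 <- w155*w282
  w369 <- w140*w31
  w370 <- w148*w155*w56
  w371 <- w160*w31
  w372 <- w146*w165
  w373 <- w150*w155*w56
  w374 <- w151*w164
  w375 <- w149*w165
  w376 <- w100*w298
  w377 <- w117*w298
  w378 <- v5*w73
  w379 <- v5*w87
  w380 <- w100*w379
  w381 <- w117*w379
  w382 <- ITH*a4 - fx1*w155 - fx2*w155 - fy1*w31 - fy2*w31 + w100*w155*w378 - w113*w155 + w117*w155*w378 - w118*w155 - w124*w155 - w128*w155 - w130*w155 + w143*w31 - w155*w24 + w155*w276 + w155*w289 + w155*w291 + w155*w297 + w155*w301 + w155*w302 + w155*w338 + w155*w339 + w155*w357 + w155*w376 + w155*w377 + w155*w380 + w155*w381 - w155*w5 - w155*w58 - w155*w60 - w155*w61 - w155*w75 - w155*w89 - w155*w91 + w167*w31 + w168*w31 + w174*w31 - w176*w31 - w178*w31 - w179*w31 - w180*w31 - w185*w31 - w186*w31 - w191*w31 - w192*w31 - w197*w31 - w200*w31 - w203*w31 - w206*w31 - w209*w31 - w212*w31 - w215*w31 - w218*w31 + w223*w31 + w226*w31 + w227*w31 + w231*w31 + w234*w31 + w235*w31 + w30*w345 + w30*w356 + w31*w340 + w31*w341 + w31*w342 + w31*w343 + w344*w97 + w346*w348 + w346*w350 + w346*w352 + w346*w353 + w346*w354 + w346*w355 + w348*w349 + w349*w350 + w349*w352 + w349*w353 + w349*w354 + w349*w355 - 2*w359 - 2*w360 - 2*w361 - 2*w363 - 2*w364 - 2*w365 + 2*w366 + 2*w367 + 2*w368 + 2*w369 + 2*w370 + 2*w371 + 2*w372 + 2*w373 + 2*w374 + 2*w375
  w383 <- w98^2
  w384 <- w33^2
  w385 <- w347*w62
  w386 <- w153*w347
  w387 <- a7*w351
  w388 <- w125*w28
  w389 <- w156*w44
  w390 <- w389*w50
  w391 <- w389*w54
  w392 <- w147*w171
  w393 <- w156*w62
  w394 <- w393*w50
  w395 <- w393*w54
  w396 <- w152*w171
  w397 <- w156*w312
  w398 <- w139*w34
  w399 <- w156*w316
  w400 <- w141*w34
  w401 <- w148*w156*w63
  w402 <- w161*w34
  w403 <- w147*w170
  w404 <- w153*w156*w63
  w405 <- w154*w169
  w406 <- w152*w170
  w407 <- w100*w332
  w408 <- w119*w332
  w409 <- v8*w76
  w410 <- v8*w92
  w411 <- w100*w410
  w412 <- w119*w410
  w413 <- ITH*a7 - fx3*w156 - fx4*w156 - fy3*w34 - fy4*w34 + w100*w156*w409 - w11*w156 - w116*w156 + w119*w156*w409 - w120*w156 - w127*w156 - w131*w156 - w133*w156 + w145*w34 - w156*w29 + w156*w310 + w156*w323 + w156*w325 + w156*w331 + w156*w335 + w156*w336 + w156*w338 + w156*w339 + w156*w388 + w156*w407 + w156*w408 + w156*w411 + w156*w412 - w156*w65 - w156*w67 - w156*w68 - w156*w78 - w156*w94 - w156*w96 + w172*w34 + w173*w34 + w175*w34 - w177*w34 - w181*w34 - w182*w34 - w183*w34 - w188*w34 - w189*w34 - w194*w34 - w195*w34 - w199*w34 - w201*w34 - w205*w34 - w207*w34 - w211*w34 - w213*w34 - w217*w34 - w219*w34 + w225*w34 + w228*w34 + w229*w34 + w233*w34 + w236*w34 + w237*w34 + w33*w345 + w33*w356 + w34*w340 + w34*w341 + w34*w342 + w34*w343 + w344*w98 + w348*w383 + w348*w384 + w350*w383 + w350*w384 + w352*w383 + w352*w384 + w383*w385 + w383*w386 + w383*w387 + w384*w385 + w384*w386 + w384*w387 - 2*w390 - 2*w391 - 2*w392 - 2*w394 - 2*w395 - 2*w396 + 2*w397 + 2*w398 + 2*w399 + 2*w400 + 2*w401 + 2*w402 + 2*w403 + 2*w404 + 2*w405 + 2*w406
  w414 <- w238 + w255
  w415 <- w239 + w303
  w416 <- w121*w14
  w417 <- w416*w46
  w418 <- w122*w20
  w419 <- w101*w122
  w420 <- w105*w184 + w105*w190 + w111*w155 - w155*w417 - w155*w418 - w155*w419 + w155*w84 + w155*w88 + w32*w47 + w32*w52 - w359 - w360 - w361 - w363 - w364 - w365 + w37*w47 + w37*w52 + w372 + w375 + w414
  w421 <- w238 + w264
  w422 <- w239 + w337
  w423 <- w416*w49
  w424 <- w125*w25
  w425 <- w103*w125
  w426 <- w106*w187 + w106*w193 + w114*w156 - w156*w423 - w156*w424 - w156*w425 + w156*w85 + w156*w93 + w35*w50 + w35*w54 + w39*w50 + w39*w54 - w390 - w391 - w392 - w394 - w395 - w396 + w403 + w406 + w421
  out$res[, 1L] <- LSH*a3*mFT*w2 + LSH*a3*mFT*w8 + LSH*a4*mFT*w2 + LSH*a7*mFT*w8 + 2*LSH*mFT*v3*v5*w12 + 2*LSH*mFT*v3*v8*w17 + 2*LSH*mFT*v4*v5*w12 + 2*LSH*mFT*v7*v8*w17 + LTH*a3*mFT*w97 + LTH*a3*mFT*w98 + LTH*a3*mSH*w97 + LTH*a3*mSH*w98 + LTH*a4*mFT*w97 + LTH*a4*mSH*w97 + LTH*a7*mFT*w98 + LTH*a7*mSH*w98 + 2*a1*mFT + a1*mHAT + 2*a1*mSH + 2*a1*mTH + a3*cSH*mSH*w2 + a3*cSH*mSH*w8 + a3*cTH*mTH*w97 + a3*cTH*mTH*w98 - a3*w43 + a4*cSH*mSH*w2 + a4*cTH*mTH*w97 + a5*fcx*mFT*w46 + a5*fcy*mFT*w51 + a7*cSH*mSH*w8 + a7*cTH*mTH*w98 + a8*fcx*mFT*w49 + a8*fcy*mFT*w53 + cHAT*mHAT*w14*w99 + 2*cSH*mSH*v3*v5*w12 + 2*cSH*mSH*v3*v8*w17 + 2*cSH*mSH*v4*v5*w12 + 2*cSH*mSH*v7*v8*w17 + 2*fcx*mFT*v3*v5*w51 + 2*fcx*mFT*v3*v8*w53 + 2*fcx*mFT*v4*v5*w51 + 2*fcx*mFT*v5*v6*w51 + 2*fcx*mFT*v7*v8*w53 + 2*fcx*mFT*v8*v9*w53 + 2*fcy*mFT*v3*v4*w46 + 2*fcy*mFT*v3*v6*w46 + 2*fcy*mFT*v3*v7*w49 + 2*fcy*mFT*v3*v9*w49 + 2*fcy*mFT*v4*v6*w46 + 2*fcy*mFT*v7*v9*w49 + fcy*mFT*w14*w46 + fcy*mFT*w14*w49 + fcy*mFT*w20*w46 + fcy*mFT*w23*w46 + fcy*mFT*w25*w49 + fcy*mFT*w28*w49 + fcy*mFT*w46*w90 + fcy*mFT*w49*w95 - fx1 - fx2 - fx3 - fx4 - mFT*w105 - mFT*w106 - mSH*w105 - mSH*w106 - mSH*w36 - mSH*w38 - w102 - w104 - w107 - w108 - w109*w30 - w11 - w110*w33 - w111 - w113 - w114 - w116 - w118 - w120 - w124 - w127 - w128 - w130 - w131 - w133 - w16 - w19 - w22 - w24 - w27 - w29 - w30*w80 - w30*w81 - w31*w40 - w32 - w33*w80 - w33*w82 - w34*w40 - w35 - w37 - w39 - w44*w47 - w44*w50 - w44*w52 - w44*w54 - w47*w55 - w5 - w50*w62 - w52*w55 - w54*w62 - w58 - w60 - w61 - w65 - w67 - w68 - w70 - w71 - w74 - w75 - w77 - w78 - w84 - w85 - w88 - w89 - w91 - w93 - w94 - w96
  out$res[, 2L] <- -a3*w42*w99 + a4*w30*w79 + a7*w33*w79 - fy1 - fy2 - fy3 - fy4 + mFT*w136 + mFT*w137 + mFT*w157 + mFT*w158 + mFT*w220 + mFT*w221 + mSH*w136 + mSH*w137 + mSH*w157 + mSH*w158 + mSH*w220 + mSH*w221 + mTH*w136 + mTH*w137 + w101*w142 - w101*w184 - w101*w190 + w101*w57 + w103*w144 - w103*w187 - w103*w193 + w103*w64 + w109*w97 + w110*w98 + w134 + w135 + w138 + w139 - w14*w43 + w140 + w141 + w142*w20 + w143 + w144*w25 + w145 + w146 + w147 + w148*w31 + w148*w34 + w149 + w15*w155 + w15*w156 + w15*w3 - w15*w47 - w15*w50 - w15*w52 - w15*w54 + w15*w9 + w150*w164 + w151 + w152 + w153*w169 + w154 + w155*w40 + w156*w40 + w160 + w161 + w162*w30 + w162*w33 + w163*w51 + w163*w53 + w165*w55 - w166*w44 - w166*w55 + w167 + w168 + w170*w62 - w171*w44 - w171*w62 + w172 + w173 + w174 + w175 - w176 - w177 - w178 - w179 - w180 - w181 - w182 - w183 - w184*w20 - w185 - w186 - w187*w25 - w188 - w189 - w190*w20 - w191 - w192 - w193*w25 - w194 - w195 - w197 - w199 + w20*w57 - w200 - w201 - w203 - w205 - w206 - w207 - w209 - w211 - w212 - w213 - w215 - w217 - w218 - w219 + w223 + w225 + w226 + w227 + w228 + w229 + w231 + w233 + w234 + w235 + w236 + w237 + w25*w64 + w40*w56 + w40*w63 + w80*w97 + w80*w98 + w81*w97 + w82*w98
  out$res[, 3L] <- IHAT*a3 - a1*cHAT*mHAT*w41 - w134*w242 - w135*w242 + 2*w238 + 2*w239 + 2*w240 + w241*w41^2 + w241*w99^2 + w255 + w264 + w303 + w337 + w382 + w413
  out$res[, 4L] <- -tau1 + w240 + w382 + w414 + w415
  out$res[, 5L] <- 2*LSH*LTH*mFT*v3*v4*w2*w30 + LSH*LTH*mFT*w14*w2*w30 + LSH*LTH*mFT*w2*w20*w30 + 2*LTH*cSH*mSH*v3*v4*w2*w30 + LTH*cSH*mSH*w14*w2*w30 + LTH*cSH*mSH*w2*w20*w30 - tau2 - w102*w155 - w107*w155 - w155*w16 - w155*w22 - w155*w70 - w155*w74 - w366 - w367 - w368 - w369 - w370 - w371 - w373 - w374 - w415 - w420
  out$res[, 6L] <- -tau3 + w102*w47 + w102*w52 + w111*w3 + w124*w3 + w128*w3 + w16*w47 + w16*w52 + w22*w47 + w22*w52 + w24*w47 + w24*w52 - w279 - w280 - w281 - w283 - w284 - w285 - w286 + w287 + w288 + w290 + w292 + w293 - w3*w357 - w3*w380 - w3*w381 - w3*w417 - w3*w418 - w3*w419 + w3*w84 + w3*w88 + w3*w89 - w376*w47 - w376*w52 - w377*w47 - w377*w52 + w420
  out$res[, 7L] <- -tau4 + w240 + w413 + w421 + w422
  out$res[, 8L] <- 2*LSH*LTH*mFT*v3*v7*w33*w8 + LSH*LTH*mFT*w14*w33*w8 + LSH*LTH*mFT*w25*w33*w8 + 2*LTH*cSH*mSH*v3*v7*w33*w8 + LTH*cSH*mSH*w14*w33*w8 + LTH*cSH*mSH*w25*w33*w8 - tau5 - w104*w156 - w108*w156 - w156*w19 - w156*w27 - w156*w71 - w156*w77 - w397 - w398 - w399 - w400 - w401 - w402 - w404 - w405 - w422 - w426
  out$res[, 9L] <- -tau6 + w104*w50 + w104*w54 + w114*w9 + w127*w9 + w131*w9 + w19*w50 + w19*w54 + w27*w50 + w27*w54 + w29*w50 + w29*w54 - w313 - w314 - w315 - w317 - w318 - w319 - w320 + w321 + w322 + w324 + w326 + w327 - w388*w9 - w407*w50 - w407*w54 - w408*w50 - w408*w54 - w411*w9 - w412*w9 - w423*w9 - w424*w9 - w425*w9 + w426 + w85*w9 + w9*w93 + w9*w94
  out
}

.dyn_cpkin_val <- function(q, v, p) {
  n <- ncol(q)
  out <- list(px = matrix(0, n, 4L), py = matrix(0, n, 4L),
              vx = matrix(0, n, 4L), vy = matrix(0, n, 4L))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- LTH*sin(w0)
  w2 <- -q5 + w0
  w3 <- LSH*sin(w2)
  w4 <- q6 + w2
  w5 <- cos(w4)
  w6 <- sin(w4)
  w7 <- hx*w5 - hy*w6
  w8 <- w3 + w7
  w9 <- w1 + w8
  w10 <- LSH*cos(w2)
  w11 <- -w10
  w12 <- hx*w6
  w13 <- hy*w5
  w14 <- w12 + w13
  w15 <- w11 + w14
  w16 <- LTH*cos(w0)
  w17 <- q2 - w16
  w18 <- w10 + w16
  w19 <- -w12 - w13 + w18
  w20 <- tx*w5 - ty*w6
  w21 <- w20 + w3
  w22 <- w1 + w21
  w23 <- tx*w6
  w24 <- ty*w5
  w25 <- w23 + w24
  w26 <- w11 + w25
  w27 <- w18 - w23 - w24
  w28 <- q3 + q7
  w29 <- LTH*sin(w28)
  w30 <- -q8 + w28
  w31 <- LSH*sin(w30)
  w32 <- q9 + w30
  w33 <- cos(w32)
  w34 <- sin(w32)
  w35 <- hx*w33 - hy*w34
  w36 <- w31 + w35
  w37 <- w29 + w36
  w38 <- LSH*cos(w30)
  w39 <- -w38
  w40 <- hx*w34
  w41 <- hy*w33
  w42 <- w40 + w41
  w43 <- w39 + w42
  w44 <- LTH*cos(w28)
  w45 <- q2 - w44
  w46 <- w38 + w44
  w47 <- -w40 - w41 + w46
  w48 <- tx*w33 - ty*w34
  w49 <- w31 + w48
  w50 <- w29 + w49
  w51 <- tx*w34
  w52 <- ty*w33
  w53 <- w51 + w52
  w54 <- w39 + w53
  w55 <- w46 - w51 - w52
  out$px[, 1L] <- q1 + w9
  out$py[, 1L] <- w15 + w17
  out$vx[, 1L] <- v1 + v3*w19 + v4*w19 + v5*w15 - v6*w14
  out$vy[, 1L] <- v2 + v3*w9 + v4*w9 - v5*w8 + v6*w7
  out$px[, 2L] <- q1 + w22
  out$py[, 2L] <- w17 + w26
  out$vx[, 2L] <- v1 + v3*w27 + v4*w27 + v5*w26 - v6*w25
  out$vy[, 2L] <- v2 + v3*w22 + v4*w22 - v5*w21 + v6*w20
  out$px[, 3L] <- q1 + w37
  out$py[, 3L] <- w43 + w45
  out$vx[, 3L] <- v1 + v3*w47 + v7*w47 + v8*w43 - v9*w42
  out$vy[, 3L] <- v2 + v3*w37 + v7*w37 - v8*w36 + v9*w35
  out$px[, 4L] <- q1 + w50
  out$py[, 4L] <- w45 + w54
  out$vx[, 4L] <- v1 + v3*w55 + v7*w55 + v8*w54 - v9*w53
  out$vy[, 4L] <- v2 + v3*w50 + v7*w50 - v8*w49 + v9*w48
  out
}

.dyn_imu_hat_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- cos(q3)
  w1 <- sin(q3)
  w2 <- w0^2
  w3 <- a3*ry
  w4 <- w1^2
  w5 <- v3^2
  w6 <- rx*w5
  w7 <- a3*rx
  w8 <- ry*w5
  out$ax <- a1*w0 + a2*w1 + grav*w1 - w2*w3 - w2*w6 - w3*w4 - w4*w6
  out$ay <- -a1*w1 + a2*w0 + grav*w0 + w2*w7 - w2*w8 + w4*w7 - w4*w8
  out$wz <- v3
  out
}

.dyn_imu_thigh_r_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- cos(w0)
  w2 <- sin(w0)
  w3 <- w1^2
  w4 <- a3*ry
  w5 <- w2^2
  w6 <- a4*ry
  w7 <- v3^2
  w8 <- rx*w7
  w9 <- v4^2
  w10 <- rx*w9
  w11 <- 2*v3*v4
  w12 <- rx*w11
  w13 <- ry*w7
  w14 <- ry*w9
  w15 <- ry*w11
  out$ax <- a1*w1 + a2*w2 + grav*w2 - w10*w3 - w10*w5 - w12*w3 - w12*w5 - w3*w4 - w3*w6 - w3*w8 - w4*w5 - w5*w6 - w5*w8
  out$ay <- -a1*w2 + a2*w1 + a3*rx*w3 + a3*rx*w5 + a4*rx*w3 + a4*rx*w5 + grav*w1 - w13*w3 - w13*w5 - w14*w3 - w14*w5 - w15*w3 - w15*w5
  out$wz <- v3 + v4
  out
}

.dyn_imu_shank_r_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- -q5 + w0
  w2 <- cos(w1)
  w3 <- sin(w1)
  w4 <- w2^2
  w5 <- a5*ry
  w6 <- w3^2
  w7 <- a3*ry
  w8 <- a4*ry
  w9 <- v3^2
  w10 <- rx*w9
  w11 <- v4^2
  w12 <- rx*w11
  w13 <- v5^2
  w14 <- rx*w13
  w15 <- LTH*a3
  w16 <- cos(w0)
  w17 <- w16*w2
  w18 <- sin(w0)
  w19 <- w18*w3
  w20 <- LTH*a4
  w21 <- LTH*w9
  w22 <- w16*w3
  w23 <- LTH*w11
  w24 <- w18*w2
  w25 <- 2*v3
  w26 <- rx*w25
  w27 <- v4*w4
  w28 <- w26*w6
  w29 <- v5*w4
  w30 <- 2*v5
  w31 <- rx*w30
  w32 <- v4*w6
  w33 <- LTH*v4*w25
  w34 <- a3*rx
  w35 <- a4*rx
  w36 <- a5*rx
  w37 <- ry*w9
  w38 <- ry*w11
  w39 <- ry*w13
  w40 <- ry*w25
  w41 <- ry*w30
  out$ax <- a1*w2 + a2*w3 + grav*w3 - v4*w28 + v5*w28 - w10*w4 - w10*w6 - w12*w4 - w12*w6 - w14*w4 - w14*w6 + w15*w17 + w15*w19 + w17*w20 + w19*w20 + w21*w22 - w21*w24 + w22*w23 + w22*w33 - w23*w24 - w24*w33 - w26*w27 + w26*w29 + w27*w31 + w31*w32 + w4*w5 - w4*w7 - w4*w8 + w5*w6 - w6*w7 - w6*w8
  out$ay <- -a1*w3 + a2*w2 + grav*w2 + v5*w40*w6 - w15*w22 + w15*w24 + w17*w21 + w17*w23 + w17*w33 + w19*w21 + w19*w23 + w19*w33 - w20*w22 + w20*w24 - w27*w40 + w27*w41 + w29*w40 - w32*w40 + w32*w41 + w34*w4 + w34*w6 + w35*w4 + w35*w6 - w36*w4 - w36*w6 - w37*w4 - w37*w6 - w38*w4 - w38*w6 - w39*w4 - w39*w6
  out$wz <- v3 + v4 - v5
  out
}

.dyn_imu_foot_r_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- -q5 + w0
  w2 <- q6 + w1
  w3 <- cos(w2)
  w4 <- sin(w2)
  w5 <- w3^2
  w6 <- a3*ry
  w7 <- w4^2
  w8 <- a4*ry
  w9 <- a6*ry
  w10 <- v3^2
  w11 <- rx*w10
  w12 <- v4^2
  w13 <- rx*w12
  w14 <- v5^2
  w15 <- rx*w14
  w16 <- v6^2
  w17 <- rx*w16
  w18 <- cos(w1)
  w19 <- w18*w3
  w20 <- LSH*a5
  w21 <- sin(w1)
  w22 <- w21*w4
  w23 <- w10*w3
  w24 <- LSH*w21
  w25 <- w24*w3
  w26 <- sin(w0)
  w27 <- LTH*w26
  w28 <- w27*w3
  w29 <- cos(w0)
  w30 <- 2*rx
  w31 <- v3*w30
  w32 <- v4*w5
  w33 <- w31*w7
  w34 <- v6*w30
  w35 <- v4*w7
  w36 <- 2*v3
  w37 <- v4*w36
  w38 <- LSH*w18*w4
  w39 <- v5*w38
  w40 <- 2*v4
  w41 <- a3*rx
  w42 <- a4*rx
  w43 <- a6*rx
  w44 <- a5*rx
  w45 <- ry*w10
  w46 <- ry*w12
  w47 <- ry*w14
  w48 <- ry*w16
  w49 <- LSH*a3
  w50 <- w21*w3
  w51 <- LSH*a4
  w52 <- LSH*w10
  w53 <- LSH*w12
  w54 <- LSH*w14
  w55 <- LTH*a3
  w56 <- w26*w3
  w57 <- LTH*a4
  w58 <- LTH*w29*w3
  w59 <- LTH*w26*w4
  w60 <- w18*w4
  w61 <- w29*w4
  w62 <- 2*ry
  w63 <- v3*w62
  w64 <- v6*w63
  w65 <- v6*w62
  w66 <- v5*w63
  w67 <- v5*w62
  w68 <- v5*w65
  w69 <- LSH*v5
  w70 <- w36*w69
  w71 <- w40*w69
  w72 <- LSH*w37
  out$ax <- LSH*a3*w18*w3 + LSH*a3*w21*w4 + LSH*a4*w18*w3 + LSH*a4*w21*w4 + 2*LSH*v3*v4*w18*w4 + 2*LSH*v3*v5*w21*w3 + 2*LSH*v4*v5*w21*w3 + LSH*w10*w18*w4 + LSH*w12*w18*w4 + LSH*w14*w18*w4 + LTH*a3*w26*w4 + LTH*a3*w29*w3 + LTH*a4*w26*w4 + LTH*a4*w29*w3 + 2*LTH*v3*v4*w29*w4 + LTH*w10*w29*w4 + LTH*w12*w29*w4 + a1*w3 + a2*w4 + a5*ry*w5 + a5*ry*w7 + grav*w4 + 2*rx*v3*v5*w5 + 2*rx*v3*v5*w7 + 2*rx*v4*v5*w5 + 2*rx*v4*v5*w7 + 2*rx*v5*v6*w5 + 2*rx*v5*v6*w7 - v4*w33 - v6*w31*w5 - v6*w33 - w11*w5 - w11*w7 - w12*w25 - w12*w28 - w13*w5 - w13*w7 - w14*w25 - w15*w5 - w15*w7 - w17*w5 - w17*w7 - w19*w20 - w20*w22 - w23*w24 - w23*w27 - w25*w37 - w28*w37 - w31*w32 - w32*w34 - w34*w35 - w36*w39 - w39*w40 - w5*w6 - w5*w8 - w5*w9 - w6*w7 - w7*w8 - w7*w9
  out$ay <- -a1*w4 + a2*w3 + a5*w38 + grav*w3 + w10*w27*w4 + w10*w58 + w12*w58 + w12*w59 + w19*w52 + w19*w53 + w19*w54 - w19*w70 - w19*w71 + w19*w72 - w20*w50 + w22*w52 + w22*w53 + w22*w54 - w22*w70 - w22*w71 + w22*w72 - w32*w63 - w32*w65 + w32*w67 - w35*w63 - w35*w65 + w35*w67 + w37*w58 + w37*w59 + w41*w5 + w41*w7 + w42*w5 + w42*w7 + w43*w5 + w43*w7 - w44*w5 - w44*w7 - w45*w5 - w45*w7 - w46*w5 - w46*w7 - w47*w5 - w47*w7 - w48*w5 - w48*w7 + w49*w50 - w49*w60 - w5*w64 + w5*w66 + w5*w68 + w50*w51 - w51*w60 + w55*w56 - w55*w61 + w56*w57 - w57*w61 - w64*w7 + w66*w7 + w68*w7
  out$wz <- v3 + v4 - v5 + v6
  out
}

.dyn_imu_thigh_l_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q7
  w1 <- cos(w0)
  w2 <- sin(w0)
  w3 <- w1^2
  w4 <- a3*ry
  w5 <- w2^2
  w6 <- a7*ry
  w7 <- v3^2
  w8 <- rx*w7
  w9 <- v7^2
  w10 <- rx*w9
  w11 <- 2*v3*v7
  w12 <- rx*w11
  w13 <- ry*w7
  w14 <- ry*w9
  w15 <- ry*w11
  out$ax <- a1*w1 + a2*w2 + grav*w2 - w10*w3 - w10*w5 - w12*w3 - w12*w5 - w3*w4 - w3*w6 - w3*w8 - w4*w5 - w5*w6 - w5*w8
  out$ay <- -a1*w2 + a2*w1 + a3*rx*w3 + a3*rx*w5 + a7*rx*w3 + a7*rx*w5 + grav*w1 - w13*w3 - w13*w5 - w14*w3 - w14*w5 - w15*w3 - w15*w5
  out$wz <- v3 + v7
  out
}

.dyn_imu_shank_l_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q7
  w1 <- -q8 + w0
  w2 <- cos(w1)
  w3 <- sin(w1)
  w4 <- w2^2
  w5 <- a8*ry
  w6 <- w3^2
  w7 <- a3*ry
  w8 <- a7*ry
  w9 <- v3^2
  w10 <- rx*w9
  w11 <- v7^2
  w12 <- rx*w11
  w13 <- v8^2
  w14 <- rx*w13
  w15 <- LTH*a3
  w16 <- cos(w0)
  w17 <- w16*w2
  w18 <- sin(w0)
  w19 <- w18*w3
  w20 <- LTH*a7
  w21 <- LTH*w9
  w22 <- w16*w3
  w23 <- LTH*w11
  w24 <- w18*w2
  w25 <- 2*v3
  w26 <- rx*w25
  w27 <- v7*w4
  w28 <- w26*w6
  w29 <- v8*w4
  w30 <- 2*v8
  w31 <- rx*w30
  w32 <- v7*w6
  w33 <- LTH*v7*w25
  w34 <- a3*rx
  w35 <- a7*rx
  w36 <- a8*rx
  w37 <- ry*w9
  w38 <- ry*w11
  w39 <- ry*w13
  w40 <- ry*w25
  w41 <- ry*w30
  out$ax <- a1*w2 + a2*w3 + grav*w3 - v7*w28 + v8*w28 - w10*w4 - w10*w6 - w12*w4 - w12*w6 - w14*w4 - w14*w6 + w15*w17 + w15*w19 + w17*w20 + w19*w20 + w21*w22 - w21*w24 + w22*w23 + w22*w33 - w23*w24 - w24*w33 - w26*w27 + w26*w29 + w27*w31 + w31*w32 + w4*w5 - w4*w7 - w4*w8 + w5*w6 - w6*w7 - w6*w8
  out$ay <- -a1*w3 + a2*w2 + grav*w2 + v8*w40*w6 - w15*w22 + w15*w24 + w17*w21 + w17*w23 + w17*w33 + w19*w21 + w19*w23 + w19*w33 - w20*w22 + w20*w24 - w27*w40 + w27*w41 + w29*w40 - w32*w40 + w32*w41 + w34*w4 + w34*w6 + w35*w4 + w35*w6 - w36*w4 - w36*w6 - w37*w4 - w37*w6 - w38*w4 - w38*w6 - w39*w4 - w39*w6
  out$wz <- v3 + v7 - v8
  out
}

.dyn_imu_foot_l_val <- function(q, v, a, rx, ry, p) {
  n <- ncol(q)
  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q7
  w1 <- -q8 + w0
  w2 <- q9 + w1
  w3 <- cos(w2)
  w4 <- sin(w2)
  w5 <- w3^2
  w6 <- a3*ry
  w7 <- w4^2
  w8 <- a7*ry
  w9 <- a9*ry
  w10 <- v3^2
  w11 <- rx*w10
  w12 <- v7^2
  w13 <- rx*w12
  w14 <- v8^2
  w15 <- rx*w14
  w16 <- v9^2
  w17 <- rx*w16
  w18 <- cos(w1)
  w19 <- w18*w3
  w20 <- LSH*a8
  w21 <- sin(w1)
  w22 <- w21*w4
  w23 <- w10*w3
  w24 <- LSH*w21
  w25 <- w24*w3
  w26 <- sin(w0)
  w27 <- LTH*w26
  w28 <- w27*w3
  w29 <- cos(w0)
  w30 <- 2*rx
  w31 <- v3*w30
  w32 <- v7*w5
  w33 <- w31*w7
  w34 <- v9*w30
  w35 <- v7*w7
  w36 <- 2*v3
  w37 <- v7*w36
  w38 <- LSH*w18*w4
  w39 <- v8*w38
  w40 <- 2*v7
  w41 <- a3*rx
  w42 <- a7*rx
  w43 <- a9*rx
  w44 <- a8*rx
  w45 <- ry*w10
  w46 <- ry*w12
  w47 <- ry*w14
  w48 <- ry*w16
  w49 <- LSH*a3
  w50 <- w21*w3
  w51 <- LSH*a7
  w52 <- LSH*w10
  w53 <- LSH*w12
  w54 <- LSH*w14
  w55 <- LTH*a3
  w56 <- w26*w3
  w57 <- LTH*a7
  w58 <- LTH*w29*w3
  w59 <- LTH*w26*w4
  w60 <- w18*w4
  w61 <- w29*w4
  w62 <- 2*ry
  w63 <- v3*w62
  w64 <- v9*w63
  w65 <- v9*w62
  w66 <- v8*w63
  w67 <- v8*w62
  w68 <- v8*w65
  w69 <- LSH*v8
  w70 <- w36*w69
  w71 <- w40*w69
  w72 <- LSH*w37
  out$ax <- LSH*a3*w18*w3 + LSH*a3*w21*w4 + LSH*a7*w18*w3 + LSH*a7*w21*w4 + 2*LSH*v3*v7*w18*w4 + 2*LSH*v3*v8*w21*w3 + 2*LSH*v7*v8*w21*w3 + LSH*w10*w18*w4 + LSH*w12*w18*w4 + LSH*w14*w18*w4 + LTH*a3*w26*w4 + LTH*a3*w29*w3 + LTH*a7*w26*w4 + LTH*a7*w29*w3 + 2*LTH*v3*v7*w29*w4 + LTH*w10*w29*w4 + LTH*w12*w29*w4 + a1*w3 + a2*w4 + a8*ry*w5 + a8*ry*w7 + grav*w4 + 2*rx*v3*v8*w5 + 2*rx*v3*v8*w7 + 2*rx*v7*v8*w5 + 2*rx*v7*v8*w7 + 2*rx*v8*v9*w5 + 2*rx*v8*v9*w7 - v7*w33 - v9*w31*w5 - v9*w33 - w11*w5 - w11*w7 - w12*w25 - w12*w28 - w13*w5 - w13*w7 - w14*w25 - w15*w5 - w15*w7 - w17*w5 - w17*w7 - w19*w20 - w20*w22 - w23*w24 - w23*w27 - w25*w37 - w28*w37 - w31*w32 - w32*w34 - w34*w35 - w36*w39 - w39*w40 - w5*w6 - w5*w8 - w5*w9 - w6*w7 - w7*w8 - w7*w9
  out$ay <- -a1*w4 + a2*w3 + a8*w38 + grav*w3 + w10*w27*w4 + w10*w58 + w12*w58 + w12*w59 + w19*w52 + w19*w53 + w19*w54 - w19*w70 - w19*w71 + w19*w72 - w20*w50 + w22*w52 + w22*w53 + w22*w54 - w22*w70 - w22*w71 + w22*w72 - w32*w63 - w32*w65 + w32*w67 - w35*w63 - w35*w65 + w35*w67 + w37*w58 + w37*w59 + w41*w5 + w41*w7 + w42*w5 + w42*w7 + w43*w5 + w43*w7 - w44*w5 - w44*w7 - w45*w5 - w45*w7 - w46*w5 - w46*w7 - w47*w5 - w47*w7 - w48*w5 - w48*w7 + w49*w50 - w49*w60 - w5*w64 + w5*w66 + w5*w68 + w50*w51 - w51*w60 + w55*w56 - w55*w61 + w56*w57 - w57*w61 - w64*w7 + w66*w7 + w68*w7
  out$wz <- v3 + v7 - v8 + v9
  out
}

.dyn_imu_val_fns <- list(hat = .dyn_imu_hat_val, thigh_r = .dyn_imu_thigh_r_val, shank_r = .dyn_imu_shank_r_val, foot_r = .dyn_imu_foot_r_val, thigh_l = .dyn_imu_thigh_l_val, shank_l = .dyn_imu_shank_l_val, foot_l = .dyn_imu_foot_l_val)

.dyn_eom_whess <- function(q, v, a, f, yw, p) {
  n <- ncol(q)
  z9 <- array(0, c(n, 9L, 9L))
  out <- list(Hqq = z9, Hqv = z9, Hvv = z9, Hqa = z9,
              Hqf = array(0, c(n, 9L, 8L)))
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  a1 <- a[1L, ]
  a2 <- a[2L, ]
  a3 <- a[3L, ]
  a4 <- a[4L, ]
  a5 <- a[5L, ]
  a6 <- a[6L, ]
  a7 <- a[7L, ]
  a8 <- a[8L, ]
  a9 <- a[9L, ]
  fx1 <- f[1L, ]
  fy1 <- f[2L, ]
  fx2 <- f[3L, ]
  fy2 <- f[4L, ]
  fx3 <- f[5L, ]
  fy3 <- f[6L, ]
  fx4 <- f[7L, ]
  fy4 <- f[8L, ]
  yw1 <- yw[1L, ]
  yw2 <- yw[2L, ]
  yw3 <- yw[3L, ]
  yw4 <- yw[4L, ]
  yw5 <- yw[5L, ]
  yw6 <- yw[6L, ]
  yw7 <- yw[7L, ]
  yw8 <- yw[8L, ]
  yw9 <- yw[9L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- cHAT*mHAT
  w1 <- w0*sin(q3)
  w2 <- q3 + q4
  w3 <- sin(w2)
  w4 <- LTH*w3
  w5 <- mFT*w4
  w6 <- mSH*w4
  w7 <- cTH*mTH
  w8 <- w3*w7
  w9 <- -q5 + w2
  w10 <- sin(w9)
  w11 <- LSH*w10
  w12 <- mFT*w11
  w13 <- cSH*mSH
  w14 <- w10*w13
  w15 <- q6 + w9
  w16 <- cos(w15)
  w17 <- fcx*w16
  w18 <- mFT*w17
  w19 <- sin(w15)
  w20 <- fcy*w19
  w21 <- mFT*w20
  w22 <- w12 + w14 + w18 - w21
  w23 <- w22 + w5 + w6 + w8
  w24 <- q3 + q7
  w25 <- sin(w24)
  w26 <- LTH*w25
  w27 <- mFT*w26
  w28 <- mSH*w26
  w29 <- w25*w7
  w30 <- -q8 + w24
  w31 <- sin(w30)
  w32 <- LSH*w31
  w33 <- mFT*w32
  w34 <- w13*w31
  w35 <- q9 + w30
  w36 <- cos(w35)
  w37 <- fcx*w36
  w38 <- mFT*w37
  w39 <- sin(w35)
  w40 <- fcy*w39
  w41 <- mFT*w40
  w42 <- w33 + w34 + w38 - w41
  w43 <- w27 + w28 + w29 + w42
  w44 <- -w1 + w23 + w43
  w45 <- w17 - w20
  w46 <- mFT*yw6
  w47 <- -w22*yw5 + w45*w46
  w48 <- w23*yw4 + w47
  w49 <- w37 - w40
  w50 <- mFT*yw9
  w51 <- -w42*yw8 + w49*w50
  w52 <- w43*yw7 + w51
  w53 <- w0*cos(q3)
  w54 <- cos(w2)
  w55 <- LTH*w54
  w56 <- mFT*w55
  w57 <- mSH*w55
  w58 <- w54*w7
  w59 <- cos(w9)
  w60 <- LSH*w59
  w61 <- mFT*w60
  w62 <- w13*w59
  w63 <- fcx*w19
  w64 <- mFT*w63
  w65 <- fcy*w16
  w66 <- mFT*w65
  w67 <- w61 + w62 - w64 - w66
  w68 <- w56 + w57 + w58 + w67
  w69 <- cos(w24)
  w70 <- LTH*w69
  w71 <- mFT*w70
  w72 <- mSH*w70
  w73 <- w69*w7
  w74 <- cos(w30)
  w75 <- LSH*w74
  w76 <- mFT*w75
  w77 <- w13*w74
  w78 <- fcx*w39
  w79 <- mFT*w78
  w80 <- fcy*w36
  w81 <- mFT*w80
  w82 <- w76 + w77 - w79 - w81
  w83 <- w71 + w72 + w73 + w82
  w84 <- -w53 + w68 + w83
  w85 <- w63 + w65
  w86 <- w46*w85 + w67*yw5
  w87 <- -w68*yw4 + w86
  w88 <- w78 + w80
  w89 <- w50*w88 + w82*yw8
  w90 <- -w83*yw7 + w89
  w91 <- v3^2
  w92 <- a3*w12
  w93 <- a4*w12
  w94 <- w61*w91
  w95 <- v4^2
  w96 <- w61*w95
  w97 <- v5^2
  w98 <- w61*w97
  w99 <- a3*w14
  w100 <- a3*w18
  w101 <- a4*w14
  w102 <- a4*w18
  w103 <- a5*w21
  w104 <- a6*w18
  w105 <- w62*w91
  w106 <- w62*w95
  w107 <- w62*w97
  w108 <- a5*w12
  w109 <- a3*w21
  w110 <- a4*w21
  w111 <- a5*w14
  w112 <- a5*w18
  w113 <- a6*w21
  w114 <- w64*w91
  w115 <- w64*w95
  w116 <- w64*w97
  w117 <- v6^2
  w118 <- w117*w64
  w119 <- w66*w91
  w120 <- w66*w95
  w121 <- w66*w97
  w122 <- w117*w66
  w123 <- v3*w61
  w124 <- 2*v5
  w125 <- w123*w124
  w126 <- v4*w61
  w127 <- w124*w126
  w128 <- v3*w62
  w129 <- w124*w128
  w130 <- v4*w62
  w131 <- w124*w130
  w132 <- v3*w64
  w133 <- 2*v4
  w134 <- w132*w133
  w135 <- 2*v6
  w136 <- w132*w135
  w137 <- v4*w64
  w138 <- w135*w137
  w139 <- v3*w66
  w140 <- w133*w139
  w141 <- w135*w139
  w142 <- v4*w66
  w143 <- w135*w142
  w144 <- w123*w133
  w145 <- v3*w56
  w146 <- v3*w57
  w147 <- w128*w133
  w148 <- v3*w58
  w149 <- v5*w64
  w150 <- 2*v3
  w151 <- w149*w150
  w152 <- w133*w149
  w153 <- w135*w149
  w154 <- v5*w66
  w155 <- w150*w154
  w156 <- w133*w154
  w157 <- w135*w154
  w158 <- a3*w5 + a3*w6 + a3*w8 + a4*w5 + a4*w6 + a4*w8 + w100 + w101 + w102 + w103 + w104 + w105 + w106 + w107 - w108 - w109 - w110 - w111 - w112 - w113 - w114 - w115 - w116 - w118 - w119 - w120 - w121 - w122 - w125 - w127 - w129 - w131 + w133*w145 + w133*w146 + w133*w148 - w134 - w136 - w138 - w140 - w141 - w143 + w144 + w147 + w151 + w152 + w153 + w155 + w156 + w157 + w56*w91 + w56*w95 + w57*w91 + w57*w95 + w58*w91 + w58*w95 + w92 + w93 + w94 + w96 + w98 + w99
  w159 <- a3*w33
  w160 <- a7*w33
  w161 <- w76*w91
  w162 <- v7^2
  w163 <- w162*w76
  w164 <- v8^2
  w165 <- w164*w76
  w166 <- a3*w34
  w167 <- a3*w38
  w168 <- a7*w34
  w169 <- a7*w38
  w170 <- a8*w41
  w171 <- a9*w38
  w172 <- w77*w91
  w173 <- w162*w77
  w174 <- w164*w77
  w175 <- a8*w33
  w176 <- a3*w41
  w177 <- a7*w41
  w178 <- a8*w34
  w179 <- a8*w38
  w180 <- a9*w41
  w181 <- w79*w91
  w182 <- w162*w79
  w183 <- w164*w79
  w184 <- v9^2
  w185 <- w184*w79
  w186 <- w81*w91
  w187 <- w162*w81
  w188 <- w164*w81
  w189 <- w184*w81
  w190 <- v3*w76
  w191 <- 2*v8
  w192 <- w190*w191
  w193 <- v7*w76
  w194 <- w191*w193
  w195 <- v3*w77
  w196 <- w191*w195
  w197 <- v7*w77
  w198 <- w191*w197
  w199 <- v3*w79
  w200 <- 2*v7
  w201 <- w199*w200
  w202 <- 2*v9
  w203 <- w199*w202
  w204 <- v7*w79
  w205 <- w202*w204
  w206 <- v3*w81
  w207 <- w200*w206
  w208 <- w202*w206
  w209 <- v7*w81
  w210 <- w202*w209
  w211 <- w190*w200
  w212 <- v3*w71
  w213 <- v3*w72
  w214 <- w195*w200
  w215 <- v3*w73
  w216 <- v8*w79
  w217 <- w150*w216
  w218 <- w200*w216
  w219 <- w202*w216
  w220 <- v8*w81
  w221 <- w150*w220
  w222 <- w200*w220
  w223 <- w202*w220
  w224 <- a3*w27 + a3*w28 + a3*w29 + a7*w27 + a7*w28 + a7*w29 + w159 + w160 + w161 + w162*w71 + w162*w72 + w162*w73 + w163 + w165 + w166 + w167 + w168 + w169 + w170 + w171 + w172 + w173 + w174 - w175 - w176 - w177 - w178 - w179 - w180 - w181 - w182 - w183 - w185 - w186 - w187 - w188 - w189 - w192 - w194 - w196 - w198 + w200*w212 + w200*w213 + w200*w215 - w201 - w203 - w205 - w207 - w208 - w210 + w211 + w214 + w217 + w218 + w219 + w221 + w222 + w223 + w71*w91 + w72*w91 + w73*w91
  w225 <- hx*w19
  w226 <- fx1*w225
  w227 <- hy*w16
  w228 <- fx1*w227
  w229 <- tx*w19
  w230 <- fx2*w229
  w231 <- ty*w16
  w232 <- fx2*w231
  w233 <- hy*w19
  w234 <- fy1*w233
  w235 <- ty*w19
  w236 <- fy2*w235
  w237 <- hx*w16
  w238 <- fy1*w237
  w239 <- tx*w16
  w240 <- fy2*w239
  w241 <- a2*w18
  w242 <- grav*w18
  w243 <- a1*w64
  w244 <- a1*w66
  w245 <- a2*w21
  w246 <- grav*w21
  w247 <- w226 + w228 + w230 + w232 + w234 + w236 - w238 - w240 + w241 + w242 - w243 - w244 - w245 - w246
  w248 <- a1*w61 + a1*w62 + a2*w12 + a2*w14 - fx1*w60 - fx2*w60 - fy1*w11 - fy2*w11 + grav*w12 + grav*w14 + w247
  w249 <- a1*w56 + a1*w57 + a1*w58 + a2*w5 + a2*w6 + a2*w8 - fx1*w55 - fx2*w55 - fy1*w4 - fy2*w4 + grav*w5 + grav*w6 + grav*w8 + w248
  w250 <- hx*w39
  w251 <- fx3*w250
  w252 <- hy*w36
  w253 <- fx3*w252
  w254 <- tx*w39
  w255 <- fx4*w254
  w256 <- ty*w36
  w257 <- fx4*w256
  w258 <- hy*w39
  w259 <- fy3*w258
  w260 <- ty*w39
  w261 <- fy4*w260
  w262 <- hx*w36
  w263 <- fy3*w262
  w264 <- tx*w36
  w265 <- fy4*w264
  w266 <- a2*w38
  w267 <- grav*w38
  w268 <- a1*w79
  w269 <- a1*w81
  w270 <- a2*w41
  w271 <- grav*w41
  w272 <- w251 + w253 + w255 + w257 + w259 + w261 - w263 - w265 + w266 + w267 - w268 - w269 - w270 - w271
  w273 <- a1*w76 + a1*w77 + a2*w33 + a2*w34 - fx3*w75 - fx4*w75 - fy3*w32 - fy4*w32 + grav*w33 + grav*w34 + w272
  w274 <- a1*w71 + a1*w72 + a1*w73 + a2*w27 + a2*w28 + a2*w29 - fx3*w70 - fx4*w70 - fy3*w26 - fy4*w26 + grav*w27 + grav*w28 + grav*w29 + w273
  w275 <- w5*w91
  w276 <- w5*w95
  w277 <- v3*w5
  w278 <- w133*w277
  w279 <- v3*w6
  w280 <- v3*w8
  w281 <- a5*w61
  w282 <- w12*w91
  w283 <- w12*w95
  w284 <- w12*w97
  w285 <- a5*w62
  w286 <- w14*w91
  w287 <- w14*w95
  w288 <- w14*w97
  w289 <- w18*w91
  w290 <- w18*w95
  w291 <- w18*w97
  w292 <- w117*w18
  w293 <- a3*w61
  w294 <- a4*w61
  w295 <- a3*w62
  w296 <- a4*w62
  w297 <- w21*w91
  w298 <- w21*w95
  w299 <- w21*w97
  w300 <- w117*w21
  w301 <- v3*w12
  w302 <- w124*w301
  w303 <- v4*w12
  w304 <- w124*w303
  w305 <- v3*w14
  w306 <- w124*w305
  w307 <- v4*w14
  w308 <- w124*w307
  w309 <- v3*w18
  w310 <- w124*w309
  w311 <- v4*w18
  w312 <- w124*w311
  w313 <- v6*w18
  w314 <- w124*w313
  w315 <- v3*w21
  w316 <- w133*w315
  w317 <- w135*w315
  w318 <- v4*w21
  w319 <- w135*w318
  w320 <- w133*w301
  w321 <- w133*w305
  w322 <- w133*w309
  w323 <- w135*w309
  w324 <- w135*w311
  w325 <- v5*w21
  w326 <- w150*w325
  w327 <- w133*w325
  w328 <- w135*w325
  w329 <- a3*w64 + a3*w66 + a4*w64 + a4*w66 - a5*w64 - a5*w66 + a6*w64 + a6*w66 + w281 + w282 + w283 + w284 + w285 + w286 + w287 + w288 + w289 + w290 + w291 + w292 - w293 - w294 - w295 - w296 - w297 - w298 - w299 - w300 - w302 - w304 - w306 - w308 - w310 - w312 - w314 - w316 - w317 - w319 + w320 + w321 + w322 + w323 + w324 + w326 + w327 + w328
  w330 <- -a3*w56 - a3*w57 - a3*w58 - a4*w56 - a4*w57 - a4*w58 + w133*w279 + w133*w280 + w275 + w276 + w278 + w329 + w6*w91 + w6*w95 + w8*w91 + w8*w95
  w331 <- w27*w91
  w332 <- w162*w27
  w333 <- v3*w27
  w334 <- w200*w333
  w335 <- v3*w28
  w336 <- v3*w29
  w337 <- a8*w76
  w338 <- w33*w91
  w339 <- w162*w33
  w340 <- w164*w33
  w341 <- a8*w77
  w342 <- w34*w91
  w343 <- w162*w34
  w344 <- w164*w34
  w345 <- w38*w91
  w346 <- w162*w38
  w347 <- w164*w38
  w348 <- w184*w38
  w349 <- a3*w76
  w350 <- a7*w76
  w351 <- a3*w77
  w352 <- a7*w77
  w353 <- w41*w91
  w354 <- w162*w41
  w355 <- w164*w41
  w356 <- w184*w41
  w357 <- v3*w33
  w358 <- w191*w357
  w359 <- v7*w33
  w360 <- w191*w359
  w361 <- v3*w34
  w362 <- w191*w361
  w363 <- v7*w34
  w364 <- w191*w363
  w365 <- v3*w38
  w366 <- w191*w365
  w367 <- v7*w38
  w368 <- w191*w367
  w369 <- v9*w38
  w370 <- w191*w369
  w371 <- v3*w41
  w372 <- w200*w371
  w373 <- w202*w371
  w374 <- v7*w41
  w375 <- w202*w374
  w376 <- w200*w357
  w377 <- w200*w361
  w378 <- w200*w365
  w379 <- w202*w365
  w380 <- w202*w367
  w381 <- v8*w41
  w382 <- w150*w381
  w383 <- w200*w381
  w384 <- w202*w381
  w385 <- a3*w79 + a3*w81 + a7*w79 + a7*w81 - a8*w79 - a8*w81 + a9*w79 + a9*w81 + w337 + w338 + w339 + w340 + w341 + w342 + w343 + w344 + w345 + w346 + w347 + w348 - w349 - w350 - w351 - w352 - w353 - w354 - w355 - w356 - w358 - w360 - w362 - w364 - w366 - w368 - w370 - w372 - w373 - w375 + w376 + w377 + w378 + w379 + w380 + w382 + w383 + w384
  w386 <- -a3*w71 - a3*w72 - a3*w73 - a7*w71 - a7*w72 - a7*w73 + w162*w28 + w162*w29 + w200*w335 + w200*w336 + w28*w91 + w29*w91 + w331 + w332 + w334 + w385
  w387 <- w247*yw6
  w388 <- w248*yw5
  w389 <- w249*yw4 + w387 - w388
  w390 <- w272*yw9
  w391 <- w273*yw8
  w392 <- w274*yw7 + w390 - w391
  w393 <- v5*w61
  w394 <- v5*w62
  w395 <- v6*w64
  w396 <- v6*w66
  w397 <- v4*w56 + v4*w57 + v4*w58 + w123 + w126 + w128 + w130 - w132 - w137 - w139 - w142 + w145 + w146 + w148 + w149 + w154 - w393 - w394 - w395 - w396
  w398 <- v8*w76
  w399 <- v8*w77
  w400 <- v9*w79
  w401 <- v9*w81
  w402 <- v7*w71 + v7*w72 + v7*w73 + w190 + w193 + w195 + w197 - w199 - w204 - w206 - w209 + w212 + w213 + w215 + w216 + w220 - w398 - w399 - w400 - w401
  w403 <- v4*w5
  w404 <- v5*w12
  w405 <- v5*w14
  w406 <- v5*w18
  w407 <- v6*w21
  w408 <- w301 + w303 + w305 + w307 + w309 + w311 + w313 - w315 - w318 + w325 - w404 - w405 - w406 - w407
  w409 <- v4*w6 + v4*w8 + w277 + w279 + w280 + w403 + w408
  w410 <- v7*w27
  w411 <- v8*w33
  w412 <- v8*w34
  w413 <- v8*w38
  w414 <- v9*w41
  w415 <- w357 + w359 + w361 + w363 + w365 + w367 + w369 - w371 - w374 + w381 - w411 - w412 - w413 - w414
  w416 <- v7*w28 + v7*w29 + w333 + w335 + w336 + w410 + w415
  w417 <- w44*yw1 - w84*yw2
  w418 <- LTH*(w12*w54 + w14*w54 + w18*w54 - w21*w54 - w3*w61 - w3*w62 + w3*w64 + w3*w66)
  w419 <- w418*yw5
  w420 <- w17*w60
  w421 <- w11*w63
  w422 <- w11*w65
  w423 <- w20*w60
  w424 <- w17*w55 - w20*w55 + w4*w63 + w4*w65
  w425 <- w420 + w421 + w422 - w423 + w424
  w426 <- -mFT*w425*yw6 + w419
  w427 <- LTH*(-w25*w76 - w25*w77 + w25*w79 + w25*w81 + w33*w69 + w34*w69 + w38*w69 - w41*w69)
  w428 <- w427*yw8
  w429 <- w37*w75
  w430 <- w32*w78
  w431 <- w32*w80
  w432 <- w40*w75
  w433 <- w26*w78 + w26*w80 + w37*w70 - w40*w70
  w434 <- w429 + w430 + w431 - w432 + w433
  w435 <- -mFT*w434*yw9 + w428
  w436 <- -w158*yw2 - w249*yw3 + w330*yw1 - w389
  w437 <- -2*w397*yw1 - 2*w409*yw2
  w438 <- w23*yw1 - w68*yw2
  w439 <- -2*w426 - 2*w438
  w440 <- -w438
  w441 <- -w387
  w442 <- w329*yw1 + yw2*(-w100 - w101 - w102 - w103 - w104 - w105 - w106 - w107 + w108 + w109 + w110 + w111 + w112 + w113 + w114 + w115 + w116 + w118 + w119 + w120 + w121 + w122 + w125 + w127 + w129 + w131 + w134 + w136 + w138 + w140 + w141 + w143 - w144 - w147 - w151 - w152 - w153 - w155 - w156 - w157 - w92 - w93 - w94 - w96 - w98 - w99)
  w443 <- w248*yw3 + w248*yw4 - w388 - w441 - w442
  w444 <- yw1*(-w123 - w126 - w128 - w130 + w132 + w137 + w139 + w142 - w149 - w154 + w393 + w394 + w395 + w396)
  w445 <- w408*yw2
  w446 <- -2*w444 + 2*w445
  w447 <- w10*w63 + w10*w65 + w17*w59 - w20*w59
  w448 <- LSH*w447
  w449 <- w418*yw3
  w450 <- w418*yw4
  w451 <- w22*yw1 - w67*yw2
  w452 <- w449 + w450 + w451
  w453 <- -w448*w46 + w452
  w454 <- 2*w453
  w455 <- a3*w63
  w456 <- a3*w65
  w457 <- a4*w63
  w458 <- a4*w65
  w459 <- a6*w63
  w460 <- a6*w65
  w461 <- a5*w63
  w462 <- a5*w65
  w463 <- v3*w17
  w464 <- v4*w17
  w465 <- v6*w17
  w466 <- v3*w20
  w467 <- 2*w466
  w468 <- v4*w20
  w469 <- v5*w20
  w470 <- mFT*yw1
  w471 <- a3*w20
  w472 <- a4*w20
  w473 <- a5*w17
  w474 <- a6*w20
  w475 <- w63*w91
  w476 <- w63*w95
  w477 <- w63*w97
  w478 <- w117*w63
  w479 <- w65*w91
  w480 <- w65*w95
  w481 <- w65*w97
  w482 <- w117*w65
  w483 <- a3*w17
  w484 <- a4*w17
  w485 <- a5*w20
  w486 <- a6*w17
  w487 <- v3*w63
  w488 <- w124*w487
  w489 <- v4*w63
  w490 <- w124*w489
  w491 <- v6*w63
  w492 <- w124*w491
  w493 <- v3*w65
  w494 <- w124*w493
  w495 <- v4*w65
  w496 <- w124*w495
  w497 <- v6*w65
  w498 <- w124*w497
  w499 <- w135*w487
  w500 <- w135*w489
  w501 <- w135*w493
  w502 <- w135*w495
  w503 <- mFT*yw2
  w504 <- w470*(-v4*w467 - v6*w467 + w117*w17 - w117*w20 - w124*w463 - w124*w464 - w124*w465 + w133*w463 + w133*w469 + w135*w463 + w135*w464 - w135*w468 + w135*w469 + w150*w469 + w17*w91 + w17*w95 + w17*w97 - w20*w91 - w20*w95 - w20*w97 + w455 + w456 + w457 + w458 + w459 + w460 - w461 - w462) + w503*(w133*w487 + w133*w493 + w471 + w472 + w473 + w474 + w475 + w476 + w477 + w478 + w479 + w480 + w481 + w482 - w483 - w484 - w485 - w486 - w488 - w490 - w492 - w494 - w496 - w498 + w499 + w500 + w501 + w502)
  w505 <- -w247*yw3 - w247*yw4 + w247*yw5 + w441 + w504
  w506 <- v5*w63
  w507 <- v5*w65
  w508 <- yw1*(w487 + w489 + w491 + w493 + w495 + w497 - w506 - w507)
  w509 <- v5*w17
  w510 <- v6*w20
  w511 <- yw2*(w463 + w464 + w465 - w466 - w468 + w469 - w509 - w510)
  w512 <- w508 - w511
  w513 <- 2*mFT
  w514 <- w512*w513
  w515 <- w425*yw3
  w516 <- w425*yw4
  w517 <- w45*yw1 + w85*yw2
  w518 <- -LSH*w447*yw5 + w515 + w516 + w517
  w519 <- -mFT*w518
  w520 <- 2*w519
  w521 <- -mFT*w517
  w522 <- -w224*yw2 - w274*yw3 + w386*yw1 - w392
  w523 <- -2*w402*yw1 - 2*w416*yw2
  w524 <- w43*yw1 - w83*yw2
  w525 <- -2*w435 - 2*w524
  w526 <- -w524
  w527 <- -w390
  w528 <- w385*yw1 + yw2*(-w159 - w160 - w161 - w163 - w165 - w166 - w167 - w168 - w169 - w170 - w171 - w172 - w173 - w174 + w175 + w176 + w177 + w178 + w179 + w180 + w181 + w182 + w183 + w185 + w186 + w187 + w188 + w189 + w192 + w194 + w196 + w198 + w201 + w203 + w205 + w207 + w208 + w210 - w211 - w214 - w217 - w218 - w219 - w221 - w222 - w223)
  w529 <- w273*yw3 + w273*yw7 - w391 - w527 - w528
  w530 <- yw1*(-w190 - w193 - w195 - w197 + w199 + w204 + w206 + w209 - w216 - w220 + w398 + w399 + w400 + w401)
  w531 <- w415*yw2
  w532 <- -2*w530 + 2*w531
  w533 <- w31*w78 + w31*w80 + w37*w74 - w40*w74
  w534 <- LSH*w533
  w535 <- w427*yw3
  w536 <- w427*yw7
  w537 <- w42*yw1 - w82*yw2
  w538 <- w535 + w536 + w537
  w539 <- -w50*w534 + w538
  w540 <- 2*w539
  w541 <- a3*w78
  w542 <- a3*w80
  w543 <- a7*w78
  w544 <- a7*w80
  w545 <- a9*w78
  w546 <- a9*w80
  w547 <- a8*w78
  w548 <- a8*w80
  w549 <- v3*w37
  w550 <- v7*w37
  w551 <- v9*w37
  w552 <- v3*w40
  w553 <- 2*w552
  w554 <- v7*w40
  w555 <- v8*w40
  w556 <- a3*w40
  w557 <- a7*w40
  w558 <- a8*w37
  w559 <- a9*w40
  w560 <- w78*w91
  w561 <- w162*w78
  w562 <- w164*w78
  w563 <- w184*w78
  w564 <- w80*w91
  w565 <- w162*w80
  w566 <- w164*w80
  w567 <- w184*w80
  w568 <- a3*w37
  w569 <- a7*w37
  w570 <- a8*w40
  w571 <- a9*w37
  w572 <- v3*w78
  w573 <- w191*w572
  w574 <- v7*w78
  w575 <- w191*w574
  w576 <- v9*w78
  w577 <- w191*w576
  w578 <- v3*w80
  w579 <- w191*w578
  w580 <- v7*w80
  w581 <- w191*w580
  w582 <- v9*w80
  w583 <- w191*w582
  w584 <- w202*w572
  w585 <- w202*w574
  w586 <- w202*w578
  w587 <- w202*w580
  w588 <- w470*(-v7*w553 - v9*w553 + w150*w555 + w162*w37 - w162*w40 + w164*w37 - w164*w40 + w184*w37 - w184*w40 - w191*w549 - w191*w550 - w191*w551 + w200*w549 + w200*w555 + w202*w549 + w202*w550 - w202*w554 + w202*w555 + w37*w91 - w40*w91 + w541 + w542 + w543 + w544 + w545 + w546 - w547 - w548) + w503*(w200*w572 + w200*w578 + w556 + w557 + w558 + w559 + w560 + w561 + w562 + w563 + w564 + w565 + w566 + w567 - w568 - w569 - w570 - w571 - w573 - w575 - w577 - w579 - w581 - w583 + w584 + w585 + w586 + w587)
  w589 <- -w272*yw3 - w272*yw7 + w272*yw8 + w527 + w588
  w590 <- v8*w78
  w591 <- v8*w80
  w592 <- yw1*(w572 + w574 + w576 + w578 + w580 + w582 - w590 - w591)
  w593 <- v8*w37
  w594 <- v9*w40
  w595 <- yw2*(w549 + w550 + w551 - w552 - w554 + w555 - w593 - w594)
  w596 <- w592 - w595
  w597 <- w513*w596
  w598 <- w434*yw3
  w599 <- w434*yw7
  w600 <- w49*yw1 + w88*yw2
  w601 <- -LSH*w533*yw8 + w598 + w599 + w600
  w602 <- -mFT*w601
  w603 <- 2*w602
  w604 <- -mFT*w600
  w605 <- w123*w54 + w126*w54 + w128*w54 + w130*w54 - w132*w54 - w137*w54 - w139*w54 - w142*w54 + w3*w301 + w3*w303 + w3*w305 + w3*w307 + w3*w309 + w3*w311 - w3*w315 - w3*w318
  w606 <- w393*w54
  w607 <- w3*w404
  w608 <- w394*w54
  w609 <- w3*w405
  w610 <- w3*w406
  w611 <- w395*w54
  w612 <- w396*w54
  w613 <- w3*w407
  w614 <- w149*w54
  w615 <- w3*w313
  w616 <- w154*w54
  w617 <- w3*w325
  w618 <- LTH*(w606 + w607 + w608 + w609 + w610 + w611 + w612 + w613 - w614 - w615 - w616 - w617)
  w619 <- -w3*w463 - w3*w464 + w3*w466 + w3*w468 + w487*w54 + w489*w54 + w493*w54 + w495*w54
  w620 <- -w444 + w445
  w621 <- 2*LTH*w46*w619 + 2*LTH*w605*yw5 - 2*w618*yw3 - 2*w618*yw4 + 2*w620
  w622 <- LTH*(w17*w54 - w20*w54 + w3*w63 + w3*w65)
  w623 <- -w419 + 2*w449 + 2*w450 + w451 + w46*w622
  w624 <- w293*w55
  w625 <- w4*w92
  w626 <- w294*w55
  w627 <- w4*w93
  w628 <- w295*w55
  w629 <- w4*w99
  w630 <- w296*w55
  w631 <- w101*w4
  w632 <- w100*w4
  w633 <- w102*w4
  w634 <- w289*w55
  w635 <- w475*w5
  w636 <- w290*w55
  w637 <- w476*w5
  w638 <- w479*w5
  w639 <- w480*w5
  w640 <- w455*w56
  w641 <- w456*w56
  w642 <- w109*w4
  w643 <- w457*w56
  w644 <- w458*w56
  w645 <- w110*w4
  w646 <- w297*w55
  w647 <- w298*w55
  w648 <- w316*w55
  w649 <- w322*w55
  w650 <- 2*w403
  w651 <- w487*w650
  w652 <- w493*w650
  w653 <- w632 + w633 + w634 + w635 + w636 + w637 + w638 + w639 - w640 - w641 - w642 - w643 - w644 - w645 - w646 - w647 - w648 + w649 + w651 + w652
  w654 <- w461*w56
  w655 <- w462*w56
  w656 <- w103*w4
  w657 <- w104*w4
  w658 <- w299*w55
  w659 <- w300*w55
  w660 <- w112*w4
  w661 <- w459*w56
  w662 <- w460*w56
  w663 <- w113*w4
  w664 <- w291*w55
  w665 <- w477*w5
  w666 <- w292*w55
  w667 <- w478*w5
  w668 <- w481*w5
  w669 <- w482*w5
  w670 <- 2*w640
  w671 <- 2*w641
  w672 <- 2*w642
  w673 <- 2*w643
  w674 <- 2*w644
  w675 <- 2*w645
  w676 <- 2*w632
  w677 <- 2*w633
  w678 <- w124*w60
  w679 <- w323*w55
  w680 <- w499*w5
  w681 <- w324*w55
  w682 <- w5*w500
  w683 <- w326*w55
  w684 <- w5*w501
  w685 <- w327*w55
  w686 <- w5*w502
  w687 <- w328*w55
  w688 <- w310*w55
  w689 <- w488*w5
  w690 <- w312*w55
  w691 <- w490*w5
  w692 <- w314*w55
  w693 <- w492*w5
  w694 <- w494*w5
  w695 <- w317*w55
  w696 <- w496*w5
  w697 <- w319*w55
  w698 <- w498*w5
  w699 <- w107*w4 - w108*w4 - w111*w4 - w129*w4 - w131*w4 + w248 - w277*w678 - w281*w55 - w284*w55 - w285*w55 - w288*w55 + w302*w55 + w304*w55 + w306*w55 + w308*w55 - w403*w678 + w5*w60*w97 + 2*w624 + 2*w625 + 2*w626 + 2*w627 + 2*w628 + 2*w629 + 2*w630 + 2*w631 + w654 + w655 + w656 + w657 + w658 + w659 - w660 - w661 - w662 - w663 - w664 - w665 - w666 - w667 - w668 - w669 - w670 - w671 - w672 - w673 - w674 - w675 + w676 + w677 - w679 - w680 - w681 - w682 - w683 - w684 - w685 - w686 - w687 + w688 + w689 + w690 + w691 + w692 + w693 + w694 + w695 + w696 + w697 + w698
  w700 <- w247 + w653
  w701 <- -w700*yw6
  w702 <- LTH*(w605 - w606 - w607 - w608 - w609 - w610 - w611 - w612 - w613 + w614 + w615 + w616 + w617)
  w703 <- -w226 - w228 - w230 - w232 - w234 - w236 + w238 + w240 - w241 - w242 + w243 + w244 + w245 + w246
  w704 <- -w654 - w655 - w656 - w657 - w658 - w659 + w660 + w661 + w662 + w663 + w664 + w665 + w666 + w667 + w668 + w669 + w670 + w671 + w672 + w673 + w674 + w675 - w676 - w677 + w679 + w680 + w681 + w682 + w683 + w684 + w685 + w686 + w687 - w688 - w689 - w690 - w691 - w692 - w693 - w694 - w695 - w696 - w697 - w698 + w703
  w705 <- -w504 - w700*yw5 - w701 - w704*yw3 - w704*yw4
  w706 <- LTH*(-w3*w465 - w3*w469 + w3*w509 + w3*w510 + w491*w54 + w497*w54 - w506*w54 - w507*w54 + w619)
  w707 <- w513*w518
  w708 <- yw3 + yw4 - yw5 + yw6
  w709 <- -mFT*w708
  w710 <- w491*w60
  w711 <- w497*w60
  w712 <- w11*w510
  w713 <- w11*w465
  w714 <- -w4*w465 - w4*w469 + w4*w509 + w4*w510 + w491*w55 + w497*w55 - w506*w55 - w507*w55 + w710 + w711 + w712 - w713
  w715 <- -w4*w463 - w4*w464 + w4*w466 + w4*w468 + w487*w55 + w489*w55 + w493*w55 + w495*w55
  w716 <- -w11*w463 - w11*w464 + w11*w466 + w11*w468 - w11*w469 + w11*w509 + w487*w60 + w489*w60 + w493*w60 + w495*w60 - w506*w60 - w507*w60 + w715
  w717 <- w513*(w512 + w714*yw3 + w714*yw4 - w716*yw6 + yw5*(-w710 - w711 - w712 + w713 + w715))
  w718 <- 2*w420 + 2*w421 + 2*w422 - 2*w423 + w424
  w719 <- mFT*(-w425*yw6 - 2*w515 - 2*w516 - w517 + w718*yw5)
  w720 <- w714 + w715
  w721 <- -w10*w463 - w10*w464 + w10*w466 + w10*w468 - w10*w469 + w10*w509 + w487*w59 + w489*w59 + w493*w59 + w495*w59 - w506*w59 - w507*w59
  w722 <- LSH*yw5
  w723 <- w12*w483
  w724 <- w12*w484
  w725 <- w461*w61
  w726 <- w462*w61
  w727 <- w12*w485
  w728 <- w455*w61
  w729 <- w456*w61
  w730 <- w12*w471
  w731 <- w457*w61
  w732 <- w458*w61
  w733 <- w12*w472
  w734 <- w12*w473
  w735 <- 2*w404
  w736 <- w12*w474 + w12*w478 + w12*w482 - w12*w486 + w12*w499 + w12*w500 + w12*w501 + w12*w502 + w292*w60 - w300*w60 - w314*w60 - w317*w60 - w319*w60 + w323*w60 + w324*w60 + w328*w60 + w459*w61 + w460*w61 - w491*w735 - w497*w735 - 2*w723 - 2*w724 - 2*w725 - 2*w726 - 2*w727 + 2*w728 + 2*w729 + 2*w730 + 2*w731 + 2*w732 + 2*w733 + 2*w734
  w737 <- w704 + w736
  w738 <- 2*w303
  w739 <- w714 + w716
  w740 <- w190*w69 + w193*w69 + w195*w69 + w197*w69 - w199*w69 - w204*w69 - w206*w69 - w209*w69 + w25*w357 + w25*w359 + w25*w361 + w25*w363 + w25*w365 + w25*w367 - w25*w371 - w25*w374
  w741 <- w398*w69
  w742 <- w25*w411
  w743 <- w399*w69
  w744 <- w25*w412
  w745 <- w25*w413
  w746 <- w400*w69
  w747 <- w401*w69
  w748 <- w25*w414
  w749 <- w216*w69
  w750 <- w25*w369
  w751 <- w220*w69
  w752 <- w25*w381
  w753 <- LTH*(w741 + w742 + w743 + w744 + w745 + w746 + w747 + w748 - w749 - w750 - w751 - w752)
  w754 <- -w25*w549 - w25*w550 + w25*w552 + w25*w554 + w572*w69 + w574*w69 + w578*w69 + w580*w69
  w755 <- -w530 + w531
  w756 <- 2*LTH*w50*w754 + 2*LTH*w740*yw8 - 2*w753*yw3 - 2*w753*yw7 + 2*w755
  w757 <- LTH*(w25*w78 + w25*w80 + w37*w69 - w40*w69)
  w758 <- -w428 + w50*w757 + 2*w535 + 2*w536 + w537
  w759 <- w349*w70
  w760 <- w159*w26
  w761 <- w350*w70
  w762 <- w160*w26
  w763 <- w351*w70
  w764 <- w166*w26
  w765 <- w352*w70
  w766 <- w168*w26
  w767 <- w167*w26
  w768 <- w169*w26
  w769 <- w345*w70
  w770 <- w27*w560
  w771 <- w346*w70
  w772 <- w27*w561
  w773 <- w27*w564
  w774 <- w27*w565
  w775 <- w541*w71
  w776 <- w542*w71
  w777 <- w176*w26
  w778 <- w543*w71
  w779 <- w544*w71
  w780 <- w177*w26
  w781 <- w353*w70
  w782 <- w354*w70
  w783 <- w372*w70
  w784 <- w378*w70
  w785 <- 2*w410
  w786 <- w572*w785
  w787 <- w578*w785
  w788 <- w767 + w768 + w769 + w770 + w771 + w772 + w773 + w774 - w775 - w776 - w777 - w778 - w779 - w780 - w781 - w782 - w783 + w784 + w786 + w787
  w789 <- w547*w71
  w790 <- w548*w71
  w791 <- w170*w26
  w792 <- w171*w26
  w793 <- w355*w70
  w794 <- w356*w70
  w795 <- w179*w26
  w796 <- w545*w71
  w797 <- w546*w71
  w798 <- w180*w26
  w799 <- w347*w70
  w800 <- w27*w562
  w801 <- w348*w70
  w802 <- w27*w563
  w803 <- w27*w566
  w804 <- w27*w567
  w805 <- 2*w775
  w806 <- 2*w776
  w807 <- 2*w777
  w808 <- 2*w778
  w809 <- 2*w779
  w810 <- 2*w780
  w811 <- 2*w767
  w812 <- 2*w768
  w813 <- w191*w75
  w814 <- w379*w70
  w815 <- w27*w584
  w816 <- w380*w70
  w817 <- w27*w585
  w818 <- w382*w70
  w819 <- w27*w586
  w820 <- w383*w70
  w821 <- w27*w587
  w822 <- w384*w70
  w823 <- w366*w70
  w824 <- w27*w573
  w825 <- w368*w70
  w826 <- w27*w575
  w827 <- w370*w70
  w828 <- w27*w577
  w829 <- w27*w579
  w830 <- w373*w70
  w831 <- w27*w581
  w832 <- w375*w70
  w833 <- w27*w583
  w834 <- w164*w27*w75 + w174*w26 - w175*w26 - w178*w26 - w196*w26 - w198*w26 + w273 - w333*w813 - w337*w70 - w340*w70 - w341*w70 - w344*w70 + w358*w70 + w360*w70 + w362*w70 + w364*w70 - w410*w813 + 2*w759 + 2*w760 + 2*w761 + 2*w762 + 2*w763 + 2*w764 + 2*w765 + 2*w766 + w789 + w790 + w791 + w792 + w793 + w794 - w795 - w796 - w797 - w798 - w799 - w800 - w801 - w802 - w803 - w804 - w805 - w806 - w807 - w808 - w809 - w810 + w811 + w812 - w814 - w815 - w816 - w817 - w818 - w819 - w820 - w821 - w822 + w823 + w824 + w825 + w826 + w827 + w828 + w829 + w830 + w831 + w832 + w833
  w835 <- w272 + w788
  w836 <- -w835*yw9
  w837 <- LTH*(w740 - w741 - w742 - w743 - w744 - w745 - w746 - w747 - w748 + w749 + w750 + w751 + w752)
  w838 <- -w251 - w253 - w255 - w257 - w259 - w261 + w263 + w265 - w266 - w267 + w268 + w269 + w270 + w271
  w839 <- -w789 - w790 - w791 - w792 - w793 - w794 + w795 + w796 + w797 + w798 + w799 + w800 + w801 + w802 + w803 + w804 + w805 + w806 + w807 + w808 + w809 + w810 - w811 - w812 + w814 + w815 + w816 + w817 + w818 + w819 + w820 + w821 + w822 - w823 - w824 - w825 - w826 - w827 - w828 - w829 - w830 - w831 - w832 - w833 + w838
  w840 <- -w588 - w835*yw8 - w836 - w839*yw3 - w839*yw7
  w841 <- LTH*(-w25*w551 - w25*w555 + w25*w593 + w25*w594 + w576*w69 + w582*w69 - w590*w69 - w591*w69 + w754)
  w842 <- w513*w601
  w843 <- yw3 + yw7 - yw8 + yw9
  w844 <- -mFT*w843
  w845 <- w576*w75
  w846 <- w582*w75
  w847 <- w32*w594
  w848 <- w32*w551
  w849 <- -w26*w551 - w26*w555 + w26*w593 + w26*w594 + w576*w70 + w582*w70 - w590*w70 - w591*w70 + w845 + w846 + w847 - w848
  w850 <- -w26*w549 - w26*w550 + w26*w552 + w26*w554 + w572*w70 + w574*w70 + w578*w70 + w580*w70
  w851 <- -w32*w549 - w32*w550 + w32*w552 + w32*w554 - w32*w555 + w32*w593 + w572*w75 + w574*w75 + w578*w75 + w580*w75 - w590*w75 - w591*w75 + w850
  w852 <- w513*(w596 + w849*yw3 + w849*yw7 - w851*yw9 + yw8*(-w845 - w846 - w847 + w848 + w850))
  w853 <- 2*w429 + 2*w430 + 2*w431 - 2*w432 + w433
  w854 <- mFT*(-w434*yw9 - 2*w598 - 2*w599 - w600 + w853*yw8)
  w855 <- w849 + w850
  w856 <- -w31*w549 - w31*w550 + w31*w552 + w31*w554 - w31*w555 + w31*w593 + w572*w74 + w574*w74 + w578*w74 + w580*w74 - w590*w74 - w591*w74
  w857 <- LSH*yw8
  w858 <- w33*w568
  w859 <- w33*w569
  w860 <- w547*w76
  w861 <- w548*w76
  w862 <- w33*w570
  w863 <- w541*w76
  w864 <- w542*w76
  w865 <- w33*w556
  w866 <- w543*w76
  w867 <- w544*w76
  w868 <- w33*w557
  w869 <- w33*w558
  w870 <- 2*w411
  w871 <- w33*w559 + w33*w563 + w33*w567 - w33*w571 + w33*w584 + w33*w585 + w33*w586 + w33*w587 + w348*w75 - w356*w75 - w370*w75 - w373*w75 - w375*w75 + w379*w75 + w380*w75 + w384*w75 + w545*w76 + w546*w76 - w576*w870 - w582*w870 - 2*w858 - 2*w859 - 2*w860 - 2*w861 - 2*w862 + 2*w863 + 2*w864 + 2*w865 + 2*w866 + 2*w867 + 2*w868 + 2*w869
  w872 <- w839 + w871
  w873 <- 2*w359
  w874 <- w849 + w851
  w875 <- -w233 + w237
  w876 <- w11 + w875
  w877 <- w4 + w876
  w878 <- w875*yw6 - w876*yw5
  w879 <- w877*yw3 + w877*yw4 + w878
  w880 <- w55 + w60
  w881 <- -w225 - w227 + w880
  w882 <- -w60
  w883 <- w225 + w227
  w884 <- w882 + w883
  w885 <- w884*yw5
  w886 <- w883*yw6
  w887 <- -w881*yw3 - w881*yw4 - w885 + w886
  w888 <- -w235 + w239
  w889 <- w11 + w888
  w890 <- w4 + w889
  w891 <- w888*yw6 - w889*yw5
  w892 <- w890*yw3 + w890*yw4 + w891
  w893 <- -w229 - w231 + w880
  w894 <- w229 + w231
  w895 <- w882 + w894
  w896 <- w895*yw5
  w897 <- w894*yw6
  w898 <- -w893*yw3 - w893*yw4 - w896 + w897
  w899 <- -w258 + w262
  w900 <- w32 + w899
  w901 <- w26 + w900
  w902 <- w899*yw9 - w900*yw8
  w903 <- w901*yw3 + w901*yw7 + w902
  w904 <- w70 + w75
  w905 <- -w250 - w252 + w904
  w906 <- -w75
  w907 <- w250 + w252
  w908 <- w906 + w907
  w909 <- w908*yw8
  w910 <- w907*yw9
  w911 <- -w905*yw3 - w905*yw7 - w909 + w910
  w912 <- -w260 + w264
  w913 <- w32 + w912
  w914 <- w26 + w913
  w915 <- w912*yw9 - w913*yw8
  w916 <- w914*yw3 + w914*yw7 + w915
  w917 <- -w254 - w256 + w904
  w918 <- w254 + w256
  w919 <- w906 + w918
  w920 <- w919*yw8
  w921 <- w918*yw9
  w922 <- -w917*yw3 - w917*yw7 - w920 + w921
  out$Hqa[, 3L, 1L] <- -w44*yw3 - w48 - w52
  out$Hqa[, 3L, 2L] <- w84*yw3 - w87 - w90
  out$Hqq[, 3L, 3L] <- -w389 - w392 + yw1*(a3*w53 - w1*w91 + w330 + w386) - yw2*(-a3*w1 + w158 + w224 - w53*w91) - yw3*(-a1*w53 - a2*w1 - grav*w1 + w249 + w274)
  out$Hqv[, 3L, 3L] <- -2*yw1*(-v3*w53 + w397 + w402) - 2*yw2*(-v3*w1 + w409 + w416)
  out$Hvv[, 3L, 3L] <- -2*w417 - 2*w426 - 2*w435
  out$Hqa[, 3L, 3L] <- -w417
  out$Hqq[, 3L, 4L] <- w436
  out$Hqv[, 3L, 4L] <- w437
  out$Hvv[, 3L, 4L] <- w439
  out$Hqa[, 3L, 4L] <- w440
  out$Hqq[, 3L, 5L] <- w443
  out$Hqv[, 3L, 5L] <- w446
  out$Hvv[, 3L, 5L] <- w454
  out$Hqa[, 3L, 5L] <- w451
  out$Hqq[, 3L, 6L] <- w505
  out$Hqv[, 3L, 6L] <- w514
  out$Hvv[, 3L, 6L] <- w520
  out$Hqa[, 3L, 6L] <- w521
  out$Hqq[, 3L, 7L] <- w522
  out$Hqv[, 3L, 7L] <- w523
  out$Hvv[, 3L, 7L] <- w525
  out$Hqa[, 3L, 7L] <- w526
  out$Hqq[, 3L, 8L] <- w529
  out$Hqv[, 3L, 8L] <- w532
  out$Hvv[, 3L, 8L] <- w540
  out$Hqa[, 3L, 8L] <- w537
  out$Hqq[, 3L, 9L] <- w589
  out$Hqv[, 3L, 9L] <- w597
  out$Hvv[, 3L, 9L] <- w603
  out$Hqa[, 3L, 9L] <- w604
  out$Hqa[, 4L, 1L] <- -w23*yw3 - w48
  out$Hqa[, 4L, 2L] <- w68*yw3 - w87
  out$Hqq[, 4L, 3L] <- w436
  out$Hqv[, 4L, 3L] <- w437
  out$Hvv[, 4L, 3L] <- w439
  out$Hqa[, 4L, 3L] <- w440
  out$Hqq[, 4L, 4L] <- w436
  out$Hqv[, 4L, 4L] <- w437
  out$Hvv[, 4L, 4L] <- w439
  out$Hqa[, 4L, 4L] <- w440
  out$Hqq[, 4L, 5L] <- w443
  out$Hqv[, 4L, 5L] <- w446
  out$Hvv[, 4L, 5L] <- w454
  out$Hqa[, 4L, 5L] <- w451
  out$Hqq[, 4L, 6L] <- w505
  out$Hqv[, 4L, 6L] <- w514
  out$Hvv[, 4L, 6L] <- w520
  out$Hqa[, 4L, 6L] <- w521
  out$Hqa[, 5L, 1L] <- w22*yw3 + w22*yw4 + w47
  out$Hqa[, 5L, 2L] <- -w67*yw3 - w67*yw4 + w86
  out$Hqq[, 5L, 3L] <- w443
  out$Hqv[, 5L, 3L] <- w621
  out$Hvv[, 5L, 3L] <- w454
  out$Hqa[, 5L, 3L] <- w623
  out$Hqq[, 5L, 4L] <- w443
  out$Hqv[, 5L, 4L] <- w621
  out$Hvv[, 5L, 4L] <- w454
  out$Hqa[, 5L, 4L] <- w623
  out$Hqq[, 5L, 5L] <- w442 - w699*yw3 - w699*yw4 + w701 + yw5*(-w105*w4 - w106*w4 - w147*w4 + w248 - w275*w60 - w276*w60 - w278*w60 + w282*w55 + w283*w55 + w286*w55 + w287*w55 + w320*w55 + w321*w55 + w624 + w625 + w626 + w627 + w628 + w629 + w630 + w631 + w653)
  out$Hqv[, 5L, 5L] <- -2*w620 - 2*w702*yw3 - 2*w702*yw4
  out$Hvv[, 5L, 5L] <- -2*w453
  out$Hqa[, 5L, 5L] <- -w452
  out$Hqq[, 5L, 6L] <- w705
  out$Hqv[, 5L, 6L] <- w513*(-w512 - w706*yw3 - w706*yw4)
  out$Hvv[, 5L, 6L] <- w707
  out$Hqa[, 5L, 6L] <- mFT*(w517 + w622*yw3 + w622*yw4)
  out$Hqa[, 6L, 1L] <- w45*w709
  out$Hqa[, 6L, 2L] <- w709*w85
  out$Hqq[, 6L, 3L] <- w505
  out$Hqv[, 6L, 3L] <- w717
  out$Hvv[, 6L, 3L] <- w520
  out$Hqa[, 6L, 3L] <- w719
  out$Hqq[, 6L, 4L] <- w505
  out$Hqv[, 6L, 4L] <- w717
  out$Hvv[, 6L, 4L] <- w520
  out$Hqa[, 6L, 4L] <- w719
  out$Hqq[, 6L, 5L] <- w705
  out$Hqv[, 6L, 5L] <- w513*(LSH*w721*yw6 + v6*w722*(-w10*w17 + w10*w20 + w59*w63 + w59*w65) - w508 + w511 - w720*yw3 - w720*yw4)
  out$Hvv[, 6L, 5L] <- w707
  out$Hqa[, 6L, 5L] <- mFT*(-2*w448*yw5 + w448*yw6 + w517 + w718*yw3 + w718*yw4)
  out$Hqq[, 6L, 6L] <- w504 + w737*yw3 + w737*yw4 - yw5*(-w632 - w633 - w634 - w635 - w636 - w637 - w638 - w639 + w640 + w641 + w642 + w643 + w644 + w645 + w646 + w647 + w648 - w649 - w651 - w652 + w703 + w736) - yw6*(w12*w475 + w12*w476 + w12*w477 + w12*w479 + w12*w480 + w12*w481 + w289*w60 + w290*w60 + w291*w60 - w297*w60 - w298*w60 - w299*w60 - w310*w60 - w312*w60 - w316*w60 + w322*w60 + w326*w60 + w327*w60 - w487*w735 + w487*w738 - w489*w735 - w493*w735 + w493*w738 - w495*w735 + w700 + w723 + w724 + w725 + w726 + w727 - w728 - w729 - w730 - w731 - w732 - w733 - w734)
  out$Hqv[, 6L, 6L] <- w513*(w512 - w722*(-w10*w465 + w10*w510 + w491*w59 + w497*w59 + w721) + w739*yw3 + w739*yw4)
  out$Hvv[, 6L, 6L] <- w520
  out$Hqa[, 6L, 6L] <- w519
  out$Hqa[, 7L, 1L] <- -w43*yw3 - w52
  out$Hqa[, 7L, 2L] <- w83*yw3 - w90
  out$Hqq[, 7L, 3L] <- w522
  out$Hqv[, 7L, 3L] <- w523
  out$Hvv[, 7L, 3L] <- w525
  out$Hqa[, 7L, 3L] <- w526
  out$Hqq[, 7L, 7L] <- w522
  out$Hqv[, 7L, 7L] <- w523
  out$Hvv[, 7L, 7L] <- w525
  out$Hqa[, 7L, 7L] <- w526
  out$Hqq[, 7L, 8L] <- w529
  out$Hqv[, 7L, 8L] <- w532
  out$Hvv[, 7L, 8L] <- w540
  out$Hqa[, 7L, 8L] <- w537
  out$Hqq[, 7L, 9L] <- w589
  out$Hqv[, 7L, 9L] <- w597
  out$Hvv[, 7L, 9L] <- w603
  out$Hqa[, 7L, 9L] <- w604
  out$Hqa[, 8L, 1L] <- w42*yw3 + w42*yw7 + w51
  out$Hqa[, 8L, 2L] <- -w82*yw3 - w82*yw7 + w89
  out$Hqq[, 8L, 3L] <- w529
  out$Hqv[, 8L, 3L] <- w756
  out$Hvv[, 8L, 3L] <- w540
  out$Hqa[, 8L, 3L] <- w758
  out$Hqq[, 8L, 7L] <- w529
  out$Hqv[, 8L, 7L] <- w756
  out$Hvv[, 8L, 7L] <- w540
  out$Hqa[, 8L, 7L] <- w758
  out$Hqq[, 8L, 8L] <- w528 - w834*yw3 - w834*yw7 + w836 + yw8*(-w172*w26 - w173*w26 - w214*w26 + w273 - w331*w75 - w332*w75 - w334*w75 + w338*w70 + w339*w70 + w342*w70 + w343*w70 + w376*w70 + w377*w70 + w759 + w760 + w761 + w762 + w763 + w764 + w765 + w766 + w788)
  out$Hqv[, 8L, 8L] <- -2*w755 - 2*w837*yw3 - 2*w837*yw7
  out$Hvv[, 8L, 8L] <- -2*w539
  out$Hqa[, 8L, 8L] <- -w538
  out$Hqq[, 8L, 9L] <- w840
  out$Hqv[, 8L, 9L] <- w513*(-w596 - w841*yw3 - w841*yw7)
  out$Hvv[, 8L, 9L] <- w842
  out$Hqa[, 8L, 9L] <- mFT*(w600 + w757*yw3 + w757*yw7)
  out$Hqa[, 9L, 1L] <- w49*w844
  out$Hqa[, 9L, 2L] <- w844*w88
  out$Hqq[, 9L, 3L] <- w589
  out$Hqv[, 9L, 3L] <- w852
  out$Hvv[, 9L, 3L] <- w603
  out$Hqa[, 9L, 3L] <- w854
  out$Hqq[, 9L, 7L] <- w589
  out$Hqv[, 9L, 7L] <- w852
  out$Hvv[, 9L, 7L] <- w603
  out$Hqa[, 9L, 7L] <- w854
  out$Hqq[, 9L, 8L] <- w840
  out$Hqv[, 9L, 8L] <- w513*(LSH*w856*yw9 + v9*w857*(-w31*w37 + w31*w40 + w74*w78 + w74*w80) - w592 + w595 - w855*yw3 - w855*yw7)
  out$Hvv[, 9L, 8L] <- w842
  out$Hqa[, 9L, 8L] <- mFT*(-2*w534*yw8 + w534*yw9 + w600 + w853*yw3 + w853*yw7)
  out$Hqq[, 9L, 9L] <- w588 + w872*yw3 + w872*yw7 - yw8*(-w767 - w768 - w769 - w770 - w771 - w772 - w773 - w774 + w775 + w776 + w777 + w778 + w779 + w780 + w781 + w782 + w783 - w784 - w786 - w787 + w838 + w871) - yw9*(w33*w560 + w33*w561 + w33*w562 + w33*w564 + w33*w565 + w33*w566 + w345*w75 + w346*w75 + w347*w75 - w353*w75 - w354*w75 - w355*w75 - w366*w75 - w368*w75 - w372*w75 + w378*w75 + w382*w75 + w383*w75 - w572*w870 + w572*w873 - w574*w870 - w578*w870 + w578*w873 - w580*w870 + w835 + w858 + w859 + w860 + w861 + w862 - w863 - w864 - w865 - w866 - w867 - w868 - w869)
  out$Hqv[, 9L, 9L] <- w513*(w596 - w857*(-w31*w551 + w31*w594 + w576*w74 + w582*w74 + w856) + w874*yw3 + w874*yw7)
  out$Hvv[, 9L, 9L] <- w603
  out$Hqa[, 9L, 9L] <- w602
  out$Hqf[, 3L, 1L] <- w879
  out$Hqf[, 3L, 2L] <- w887
  out$Hqf[, 3L, 3L] <- w892
  out$Hqf[, 3L, 4L] <- w898
  out$Hqf[, 3L, 5L] <- w903
  out$Hqf[, 3L, 6L] <- w911
  out$Hqf[, 3L, 7L] <- w916
  out$Hqf[, 3L, 8L] <- w922
  out$Hqf[, 4L, 1L] <- w879
  out$Hqf[, 4L, 2L] <- w887
  out$Hqf[, 4L, 3L] <- w892
  out$Hqf[, 4L, 4L] <- w898
  out$Hqf[, 5L, 1L] <- -w876*yw3 - w876*yw4 - w878
  out$Hqf[, 5L, 2L] <- -w884*yw3 - w884*yw4 + w885 - w886
  out$Hqf[, 5L, 3L] <- -w889*yw3 - w889*yw4 - w891
  out$Hqf[, 5L, 4L] <- -w895*yw3 - w895*yw4 + w896 - w897
  out$Hqf[, 6L, 1L] <- w708*w875
  out$Hqf[, 6L, 2L] <- w708*w883
  out$Hqf[, 6L, 3L] <- w708*w888
  out$Hqf[, 6L, 4L] <- w708*w894
  out$Hqf[, 7L, 5L] <- w903
  out$Hqf[, 7L, 6L] <- w911
  out$Hqf[, 7L, 7L] <- w916
  out$Hqf[, 7L, 8L] <- w922
  out$Hqf[, 8L, 5L] <- -w900*yw3 - w900*yw7 - w902
  out$Hqf[, 8L, 6L] <- -w908*yw3 - w908*yw7 + w909 - w910
  out$Hqf[, 8L, 7L] <- -w913*yw3 - w913*yw7 - w915
  out$Hqf[, 8L, 8L] <- -w919*yw3 - w919*yw7 + w920 - w921
  out$Hqf[, 9L, 5L] <- w843*w899
  out$Hqf[, 9L, 6L] <- w843*w907
  out$Hqf[, 9L, 7L] <- w843*w912
  out$Hqf[, 9L, 8L] <- w843*w918
  out
}

.dyn_cpkin_whess <- function(q, v, wpx, wpy, wvx, wvy, p) {
  n <- ncol(q)
  z9 <- array(0, c(n, 9L, 9L))
  out <- list(Hqq = z9, Hqv = z9)
  q1 <- q[1L, ]
  q2 <- q[2L, ]
  q3 <- q[3L, ]
  q4 <- q[4L, ]
  q5 <- q[5L, ]
  q6 <- q[6L, ]
  q7 <- q[7L, ]
  q8 <- q[8L, ]
  q9 <- q[9L, ]
  v1 <- v[1L, ]
  v2 <- v[2L, ]
  v3 <- v[3L, ]
  v4 <- v[4L, ]
  v5 <- v[5L, ]
  v6 <- v[6L, ]
  v7 <- v[7L, ]
  v8 <- v[8L, ]
  v9 <- v[9L, ]
  wpx1 <- wpx[1L, ]
  wpy1 <- wpy[1L, ]
  wvx1 <- wvx[1L, ]
  wvy1 <- wvy[1L, ]
  wpx2 <- wpx[2L, ]
  wpy2 <- wpy[2L, ]
  wvx2 <- wvx[2L, ]
  wvy2 <- wvy[2L, ]
  wpx3 <- wpx[3L, ]
  wpy3 <- wpy[3L, ]
  wvx3 <- wvx[3L, ]
  wvy3 <- wvy[3L, ]
  wpx4 <- wpx[4L, ]
  wpy4 <- wpy[4L, ]
  wvx4 <- wvx[4L, ]
  wvy4 <- wvy[4L, ]
  mHAT <- p$mHAT
  mTH <- p$mTH
  mSH <- p$mSH
  mFT <- p$mFT
  IHAT <- p$IHAT
  ITH <- p$ITH
  ISH <- p$ISH
  IFT <- p$IFT
  cHAT <- p$cHAT
  LTH <- p$LTH
  cTH <- p$cTH
  LSH <- p$LSH
  cSH <- p$cSH
  fcx <- p$fcx
  fcy <- p$fcy
  hx <- p$hx
  hy <- p$hy
  tx <- p$tx
  ty <- p$ty
  grav <- p$grav
  w0 <- q3 + q4
  w1 <- LTH*sin(w0)
  w2 <- -q5 + w0
  w3 <- LSH*sin(w2)
  w4 <- q6 + w2
  w5 <- cos(w4)
  w6 <- sin(w4)
  w7 <- hx*w5 - hy*w6
  w8 <- w3 + w7
  w9 <- w1 + w8
  w10 <- tx*w5 - ty*w6
  w11 <- w10 + w3
  w12 <- w1 + w11
  w13 <- hx*w6
  w14 <- hy*w5
  w15 <- LSH*cos(w2)
  w16 <- LTH*cos(w0) + w15
  w17 <- -w13 - w14 + w16
  w18 <- -w15
  w19 <- w13 + w14
  w20 <- w18 + w19
  w21 <- v5*w20
  w22 <- v6*w19
  w23 <- tx*w6
  w24 <- ty*w5
  w25 <- w16 - w23 - w24
  w26 <- w23 + w24
  w27 <- w18 + w26
  w28 <- v5*w27
  w29 <- v6*w26
  w30 <- -v5*w8 + v6*w7
  w31 <- -v5*w11 + v6*w10
  w32 <- w12*wpx2 - w17*wpy1 - w25*wpy2 + w9*wpx1 + wvx1*(v3*w17 + v4*w17 + w21 - w22) + wvx2*(v3*w25 + v4*w25 + w28 - w29) + wvy1*(v3*w9 + v4*w9 + w30) + wvy2*(v3*w12 + v4*w12 + w31)
  w33 <- q3 + q7
  w34 <- LTH*sin(w33)
  w35 <- -q8 + w33
  w36 <- LSH*sin(w35)
  w37 <- q9 + w35
  w38 <- cos(w37)
  w39 <- sin(w37)
  w40 <- hx*w38 - hy*w39
  w41 <- w36 + w40
  w42 <- w34 + w41
  w43 <- tx*w38 - ty*w39
  w44 <- w36 + w43
  w45 <- w34 + w44
  w46 <- hx*w39
  w47 <- hy*w38
  w48 <- LSH*cos(w35)
  w49 <- LTH*cos(w33) + w48
  w50 <- -w46 - w47 + w49
  w51 <- -w48
  w52 <- w46 + w47
  w53 <- w51 + w52
  w54 <- v8*w53
  w55 <- v9*w52
  w56 <- tx*w39
  w57 <- ty*w38
  w58 <- w49 - w56 - w57
  w59 <- w56 + w57
  w60 <- w51 + w59
  w61 <- v8*w60
  w62 <- v9*w59
  w63 <- -v8*w41 + v9*w40
  w64 <- -v8*w44 + v9*w43
  w65 <- w42*wpx3 + w45*wpx4 - w50*wpy3 - w58*wpy4 + wvx3*(v3*w50 + v7*w50 + w54 - w55) + wvx4*(v3*w58 + v7*w58 + w61 - w62) + wvy3*(v3*w42 + v7*w42 + w63) + wvy4*(v3*w45 + v7*w45 + w64)
  w66 <- w12*wvx2 - w17*wvy1 - w25*wvy2 + w9*wvx1
  w67 <- w42*wvx3 + w45*wvx4 - w50*wvy3 - w58*wvy4
  w68 <- -w32
  w69 <- -w66
  w70 <- w11*wpx2 + w20*wpy1 + w27*wpy2 + w8*wpx1 - wvx1*(v3*w20 + v4*w20 - w21 + w22) - wvx2*(v3*w27 + v4*w27 - w28 + w29) + wvy1*(v3*w8 + v4*w8 + w30) + wvy2*(v3*w11 + v4*w11 + w31)
  w71 <- w11*wvx2 + w20*wvy1 + w27*wvy2 + w8*wvx1
  w72 <- v3 + v4 - v5 + v6
  w73 <- w10*w72*wvy2 + w10*wpx2 - w19*w72*wvx1 + w19*wpy1 - w26*w72*wvx2 + w26*wpy2 + w7*w72*wvy1 + w7*wpx1
  w74 <- -w73
  w75 <- w10*wvx2 + w19*wvy1 + w26*wvy2 + w7*wvx1
  w76 <- -w75
  w77 <- -w65
  w78 <- -w67
  w79 <- w41*wpx3 + w44*wpx4 + w53*wpy3 + w60*wpy4 - wvx3*(v3*w53 + v7*w53 - w54 + w55) - wvx4*(v3*w60 + v7*w60 - w61 + w62) + wvy3*(v3*w41 + v7*w41 + w63) + wvy4*(v3*w44 + v7*w44 + w64)
  w80 <- w41*wvx3 + w44*wvx4 + w53*wvy3 + w60*wvy4
  w81 <- v3 + v7 - v8 + v9
  w82 <- w40*w81*wvy3 + w40*wpx3 + w43*w81*wvy4 + w43*wpx4 - w52*w81*wvx3 + w52*wpy3 - w59*w81*wvx4 + w59*wpy4
  w83 <- -w82
  w84 <- w40*wvx3 + w43*wvx4 + w52*wvy3 + w59*wvy4
  w85 <- -w84
  out$Hqq[, 3L, 3L] <- -w32 - w65
  out$Hqv[, 3L, 3L] <- -w66 - w67
  out$Hqq[, 3L, 4L] <- w68
  out$Hqv[, 3L, 4L] <- w69
  out$Hqq[, 3L, 5L] <- w70
  out$Hqv[, 3L, 5L] <- w71
  out$Hqq[, 3L, 6L] <- w74
  out$Hqv[, 3L, 6L] <- w76
  out$Hqq[, 3L, 7L] <- w77
  out$Hqv[, 3L, 7L] <- w78
  out$Hqq[, 3L, 8L] <- w79
  out$Hqv[, 3L, 8L] <- w80
  out$Hqq[, 3L, 9L] <- w83
  out$Hqv[, 3L, 9L] <- w85
  out$Hqq[, 4L, 3L] <- w68
  out$Hqv[, 4L, 3L] <- w69
  out$Hqq[, 4L, 4L] <- w68
  out$Hqv[, 4L, 4L] <- w69
  out$Hqq[, 4L, 5L] <- w70
  out$Hqv[, 4L, 5L] <- w71
  out$Hqq[, 4L, 6L] <- w74
  out$Hqv[, 4L, 6L] <- w76
  out$Hqq[, 5L, 3L] <- w70
  out$Hqv[, 5L, 3L] <- w71
  out$Hqq[, 5L, 4L] <- w70
  out$Hqv[, 5L, 4L] <- w71
  out$Hqq[, 5L, 5L] <- -w70
  out$Hqv[, 5L, 5L] <- -w71
  out$Hqq[, 5L, 6L] <- w73
  out$Hqv[, 5L, 6L] <- w75
  out$Hqq[, 6L, 3L] <- w74
  out$Hqv[, 6L, 3L] <- w76
  out$Hqq[, 6L, 4L] <- w74
  out$Hqv[, 6L, 4L] <- w76
  out$Hqq[, 6L, 5L] <- w73
  out$Hqv[, 6L, 5L] <- w75
  out$Hqq[, 6L, 6L] <- w74
  out$Hqv[, 6L, 6L] <- w76
  out$Hqq[, 7L, 3L] <- w77
  out$Hqv[, 7L, 3L] <- w78
  out$Hqq[, 7L, 7L] <- w77
  out$Hqv[, 7L, 7L] <- w78
  out$Hqq[, 7L, 8L] <- w79
  out$Hqv[, 7L, 8L] <- w80
  out$Hqq[, 7L, 9L] <- w83
  out$Hqv[, 7L, 9L] <- w85
  out$Hqq[, 8L, 3L] <- w79
  out$Hqv[, 8L, 3L] <- w80
  out$Hqq[, 8L, 7L] <- w79
  out$Hqv[, 8L, 7L] <- w80
  out$Hqq[, 8L, 8L] <- -w79
  out$Hqv[, 8L, 8L] <- -w80
  out$Hqq[, 8L, 9L] <- w82
  out$Hqv[, 8L, 9L] <- w84
  out$Hqq[, 9L, 3L] <- w83
  out$Hqv[, 9L, 3L] <- w85
  out$Hqq[, 9L, 7L] <- w83
  out$Hqv[, 9L, 7L] <- w85
  out$Hqq[, 9L, 8L] <- w82
  out$Hqv[, 9L, 8L] <- w84
  out$Hqq[, 9L, 9L] <- w83
  out$Hqv[, 9L, 9L] <- w85
  out
}

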