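#!/usr/bin/env python
"""Derive the planar 7-segment / 9-DOF skeleton dynamics symbolically and emit
vectorized R code with analytic Jacobians.

Run from the repository root:

    python tools/generate_dynamics.py > R/dynamics-generated.R

Conventions (documented in the package vignette):
  * global frame: +x forward, +y up; gravity (0, -g)
  * q = (q1..q9) = pelvis x, pelvis y, trunk angle (CCW from upright),
    R hip flexion, R knee flexion, R ankle dorsiflexion, L hip, L knee, L ankle
  * absolute segment angles (CCW from the standing reference):
      HAT     : q3
      thigh R : q3 + q4          (hip flexion rotates the distal end forward)
      shank R : q3 + q4 - q5     (knee flexion rotates the shank backward)
      foot  R : q3 + q4 - q5 + q6 (dorsiflexion lifts the toes)
    and the mirrored chain with q7, q8, q9.
  * joint moments tau1..tau6 (R hip, R knee, R ankle, L hip, L knee, L ankle)
    act to increase the corresponding joint angle.
  * contact points: R heel, R toe, L heel, L toe; forces (fx, fy) are applied
    to the foot at the model's kinematic point locations.
Residual: d/dt(dT/dv) - dT/dq + dV/dq - Q(tau, F) = 0  (9 dynamics rows).
"""

import sys
import sympy as sp
from sympy.printing.rcode import rcode

q = sp.symbols("q1:10")
v = sp.symbols("v1:10")
a = sp.symbols("a1:10")
tau = sp.symbols("tau1:7")
F = sp.symbols("fx1 fy1 fx2 fy2 fx3 fy3 fx4 fy4")

par_names = ["mHAT", "mTH", "mSH", "mFT", "IHAT", "ITH", "ISH", "IFT",
             "cHAT", "LTH", "cTH", "LSH", "cSH",
             "fcx", "fcy", "hx", "hy", "tx", "ty", "grav"]
P = {n: sp.Symbol(n) for n in par_names}

def rot(phi, rx, ry):
    c, s = sp.cos(phi), sp.sin(phi)
    return (c * rx - s * ry, s * rx + c * ry)

def ddt(e):
    out = 0
    for i in range(9):
        out += sp.diff(e, q[i]) * v[i] + sp.diff(e, v[i]) * a[i]
    return out

# --- kinematic chain ---------------------------------------------------------
hip = (q[0], q[1])
phi = {}
phi["hat"] = q[2]
phi["thigh_r"] = q[2] + q[3]
phi["shank_r"] = q[2] + q[3] - q[4]
phi["foot_r"] = q[2] + q[3] - q[4] + q[5]
phi["thigh_l"] = q[2] + q[6]
phi["shank_l"] = q[2] + q[6] - q[7]
phi["foot_l"] = q[2] + q[6] - q[7] + q[8]

def add2(p, d):
    return (p[0] + d[0], p[1] + d[1])

knee_r = add2(hip, rot(phi["thigh_r"], 0, -P["LTH"]))
ank_r = add2(knee_r, rot(phi["shank_r"], 0, -P["LSH"]))
knee_l = add2(hip, rot(phi["thigh_l"], 0, -P["LTH"]))
ank_l = add2(knee_l, rot(phi["shank_l"], 0, -P["LSH"]))

origin = {"hat": hip, "thigh_r": hip, "shank_r": knee_r, "foot_r": ank_r,
          "thigh_l": hip, "shank_l": knee_l, "foot_l": ank_l}

com = {
    "hat": add2(hip, rot(phi["hat"], 0, P["cHAT"])),
    "thigh_r": add2(hip, rot(phi["thigh_r"], 0, -P["cTH"])),
    "shank_r": add2(knee_r, rot(phi["shank_r"], 0, -P["cSH"])),
    "foot_r": add2(ank_r, rot(phi["foot_r"], P["fcx"], P["fcy"])),
    "thigh_l": add2(hip, rot(phi["thigh_l"], 0, -P["cTH"])),
    "shank_l": add2(knee_l, rot(phi["shank_l"], 0, -P["cSH"])),
    "foot_l": add2(ank_l, rot(phi["foot_l"], P["fcx"], P["fcy"])),
}
mass = {"hat": P["mHAT"], "thigh_r": P["mTH"], "shank_r": P["mSH"],
        "foot_r": P["mFT"], "thigh_l": P["mTH"], "shank_l": P["mSH"],
        "foot_l": P["mFT"]}
inert = {"hat": P["IHAT"], "thigh_r": P["ITH"], "shank_r": P["ISH"],
         "foot_r": P["IFT"], "thigh_l": P["ITH"], "shank_l": P["ISH"],
         "foot_l": P["IFT"]}

cpoints = [  # R heel, R toe, L heel, L toe
    add2(ank_r, rot(phi["foot_r"], P["hx"], P["hy"])),
    add2(ank_r, rot(phi["foot_r"], P["tx"], P["ty"])),
    add2(ank_l, rot(phi["foot_l"], P["hx"], P["hy"])),
    add2(ank_l, rot(phi["foot_l"], P["tx"], P["ty"])),
]

# --- energies and residual ---------------------------------------------------
T = 0
V = 0
for s in com:
    vx, vy = ddt(com[s][0]), ddt(com[s][1])
    w = ddt(phi[s])
    T += sp.Rational(1, 2) * mass[s] * (vx ** 2 + vy ** 2) \
        + sp.Rational(1, 2) * inert[s] * w ** 2
    V += mass[s] * P["grav"] * com[s][1]
T = sp.expand(T)

Q = [0] * 9
for j in range(6):  # joint moments on q4..q9
    Q[3 + j] += tau[j]
for k, cp in enumerate(cpoints):
    for i in range(9):
        Q[i] += sp.diff(cp[0], q[i]) * F[2 * k] + sp.diff(cp[1], q[i]) * F[2 * k + 1]

res = []
for i in range(9):
    p_i = sp.diff(T, v[i])
    r = ddt(p_i) - sp.diff(T, q[i]) + sp.diff(V, q[i]) - Q[i]
    res.append(sp.expand(r))

# Jacobians
Jq = [[sp.diff(res[i], q[j]) for j in range(9)] for i in range(9)]
Jv = [[sp.diff(res[i], v[j]) for j in range(9)] for i in range(9)]
Ja = [[sp.diff(res[i], a[j]) for j in range(9)] for i in range(9)]
Jf = [[sp.diff(res[i], F[j]) for j in range(8)] for i in range(9)]

# --- contact point kinematics ------------------------------------------------
cp_out = []   # (name, expr) pairs; positions, velocities and their q-jacobians
cp_px, cp_py, cp_vx, cp_vy = [], [], [], []
for k, cp in enumerate(cpoints):
    cp_px.append(cp[0])
    cp_py.append(cp[1])
    cp_vx.append(ddt(cp[0]))
    cp_vy.append(ddt(cp[1]))
Jpx = [[sp.diff(cp_px[k], q[j]) for j in range(9)] for k in range(4)]
Jpy = [[sp.diff(cp_py[k], q[j]) for j in range(9)] for k in range(4)]
Jvxq = [[sp.diff(cp_vx[k], q[j]) for j in range(9)] for k in range(4)]
Jvyq = [[sp.diff(cp_vy[k], q[j]) for j in range(9)] for k in range(4)]

# --- virtual sensor kinematics ----------------------------------------------
rx, ry = sp.symbols("rx ry")
imu = {}
for s in com:
    pos = add2(origin[s], rot(phi[s], rx, ry))
    acc = (ddt(ddt(pos[0])), ddt(ddt(pos[1])))
    c, ss = sp.cos(phi[s]), sp.sin(phi[s])
    sfx = acc[0]            # specific force components in global frame
    sfy = acc[1] + P["grav"]
    ax = c * sfx + ss * sfy      # rotate into the segment-aligned sensor frame
    ay = -ss * sfx + c * sfy
    wz = ddt(phi[s])
    ent = {"ax": sp.expand(ax), "ay": sp.expand(ay), "wz": wz}
    ent["Jax_q"] = [sp.diff(ent["ax"], q[j]) for j in range(9)]
    ent["Jax_v"] = [sp.diff(ent["ax"], v[j]) for j in range(9)]
    ent["Jax_a"] = [sp.diff(ent["ax"], a[j]) for j in range(9)]
    ent["Jay_q"] = [sp.diff(ent["ay"], q[j]) for j in range(9)]
    ent["Jay_v"] = [sp.diff(ent["ay"], v[j]) for j in range(9)]
    ent["Jay_a"] = [sp.diff(ent["ay"], a[j]) for j in range(9)]
    ent["Jwz_v"] = [sp.diff(ent["wz"], v[j]) for j in range(9)]
    imu[s] = ent

# --- multiplier-weighted second derivatives ----------------------------------
# S_eom = sum_i yw_i * res_i; Hessian blocks over (q, v, a, f).  res is linear
# in a given (q) and linear in f given (q), so only Hqq, Hqv, Hvv, Hqa, Hqf
# are nonzero.
yw = sp.symbols("yw1:10")
S_eom = sum(yw[i] * res[i] for i in range(9))
Hqq = [[sp.diff(S_eom, q[i], q[j]) for j in range(9)] for i in range(9)]
Hqv = [[sp.diff(S_eom, q[i], v[j]) for j in range(9)] for i in range(9)]
Hvv = [[sp.diff(S_eom, v[i], v[j]) for j in range(9)] for i in range(9)]
Hqa = [[sp.diff(S_eom, q[i], a[j]) for j in range(9)] for i in range(9)]
Hqf = [[sp.diff(S_eom, q[i], F[j]) for j in range(8)] for i in range(9)]

# S_cp = sum over points of weighted (px, py, vx, vy); Hessian over (q, v)
wpx = sp.symbols("wpx1:5"); wpy = sp.symbols("wpy1:5")
wvx = sp.symbols("wvx1:5"); wvy = sp.symbols("wvy1:5")
S_cp = sum(wpx[k] * cp_px[k] + wpy[k] * cp_py[k] +
           wvx[k] * cp_vx[k] + wvy[k] * cp_vy[k] for k in range(4))
Cqq = [[sp.diff(S_cp, q[i], q[j]) for j in range(9)] for i in range(9)]
Cqv = [[sp.diff(S_cp, q[i], v[j]) for j in range(9)] for i in range(9)]

# --- R code emission ---------------------------------------------------------
def emit_function(fh, name, args, exprs, assigns, preamble):
    """exprs: list of (target_string, sympy_expr). cse over all of them."""
    replacements, reduced = sp.cse([e for _, e in exprs], order="none",
                                   symbols=sp.numbered_symbols("w"))
    fh.write(name + " <- function(" + ", ".join(args) + ") {\n")
    fh.write(preamble)
    fh.write(assigns)
    for sym, e in replacements:
        fh.write("  " + str(sym) + " <- " + rcode(e) + "\n")
    for (tgt, _), e in zip(exprs, reduced):
        if e == 0:
            continue
        fh.write("  " + tgt + " <- " + rcode(e) + "\n")
    fh.write("  out\n}\n\n")

HDR = """# Generated by tools/generate_dynamics.py -- do not edit by hand.
# Planar 7-segment skeleton: implicit dynamics residual, contact-point
# kinematics and virtual-sensor kinematics with analytic Jacobians.
# All functions are vectorized over evaluation points (matrix columns).

"""

unpack_qva = "".join(
    [f"  q{i+1} <- q[{i+1}L, ]\n" for i in range(9)] +
    [f"  v{i+1} <- v[{i+1}L, ]\n" for i in range(9)])
unpack_a = "".join([f"  a{i+1} <- a[{i+1}L, ]\n" for i in range(9)])
unpack_par = "".join([f"  {n} <- p${n}\n" for n in par_names])

with open(sys.stdout.fileno(), "w", closefd=False) as fh:
    fh.write(HDR)

    # equations of motion
    exprs = [(f"out$res[, {i+1}L]", res[i]) for i in range(9)]
    for i in range(9):
        for j in range(9):
            exprs.append((f"out$Jq[, {i+1}L, {j+1}L]", Jq[i][j]))
    for i in range(9):
        for j in range(9):
            exprs.append((f"out$Jv[, {i+1}L, {j+1}L]", Jv[i][j]))
    for i in range(9):
        for j in range(9):
            exprs.append((f"out$Ja[, {i+1}L, {j+1}L]", Ja[i][j]))
    for i in range(9):
        for j in range(8):
            exprs.append((f"out$Jf[, {i+1}L, {j+1}L]", Jf[i][j]))
    assigns = unpack_qva + unpack_a
    assigns += "".join([f"  tau{j+1} <- tau[{j+1}L, ]\n" for j in range(6)])
    assigns += "".join([f"  {str(F[j])} <- f[{j+1}L, ]\n" for j in range(8)])
    assigns += unpack_par
    pre = ("  n <- ncol(q)\n"
           "  out <- list(res = matrix(0, n, 9L), Jq = array(0, c(n, 9L, 9L)),\n"
           "              Jv = array(0, c(n, 9L, 9L)), Ja = array(0, c(n, 9L, 9L)),\n"
           "              Jf = array(0, c(n, 9L, 8L)))\n")
    emit_function(fh, ".dyn_eom", ["q", "v", "a", "tau", "f", "p"],
                  exprs, assigns, pre)

    # contact point kinematics
    exprs = []
    for k in range(4):
        exprs.append((f"out$px[, {k+1}L]", cp_px[k]))
        exprs.append((f"out$py[, {k+1}L]", cp_py[k]))
        exprs.append((f"out$vx[, {k+1}L]", cp_vx[k]))
        exprs.append((f"out$vy[, {k+1}L]", cp_vy[k]))
    for k in range(4):
        for j in range(9):
            exprs.append((f"out$Jpx[, {k+1}L, {j+1}L]", Jpx[k][j]))
            exprs.append((f"out$Jpy[, {k+1}L, {j+1}L]", Jpy[k][j]))
            exprs.append((f"out$Jvx[, {k+1}L, {j+1}L]", Jvxq[k][j]))
            exprs.append((f"out$Jvy[, {k+1}L, {j+1}L]", Jvyq[k][j]))
    pre = ("  n <- ncol(q)\n"
           "  out <- list(px = matrix(0, n, 4L), py = matrix(0, n, 4L),\n"
           "              vx = matrix(0, n, 4L), vy = matrix(0, n, 4L),\n"
           "              Jpx = array(0, c(n, 4L, 9L)), Jpy = array(0, c(n, 4L, 9L)),\n"
           "              Jvx = array(0, c(n, 4L, 9L)), Jvy = array(0, c(n, 4L, 9L)))\n")
    emit_function(fh, ".dyn_cpkin", ["q", "v", "p"], exprs, unpack_qva + unpack_par, pre)

    # virtual sensors, one function per host segment
    for s, ent in imu.items():
        exprs = [("out$ax", ent["ax"]), ("out$ay", ent["ay"]), ("out$wz", ent["wz"])]
        for j in range(9):
            exprs.append((f"out$Jax_q[, {j+1}L]", ent["Jax_q"][j]))
            exprs.append((f"out$Jax_v[, {j+1}L]", ent["Jax_v"][j]))
            exprs.append((f"out$Jax_a[, {j+1}L]", ent["Jax_a"][j]))
            exprs.append((f"out$Jay_q[, {j+1}L]", ent["Jay_q"][j]))
            exprs.append((f"out$Jay_v[, {j+1}L]", ent["Jay_v"][j]))
            exprs.append((f"out$Jay_a[, {j+1}L]", ent["Jay_a"][j]))
            exprs.append((f"out$Jwz_v[, {j+1}L]", ent["Jwz_v"][j]))
        pre = ("  n <- ncol(q)\n"
               "  z <- matrix(0, n, 9L)\n"
               "  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n),\n"
               "              Jax_q = z, Jax_v = z, Jax_a = z,\n"
               "              Jay_q = z, Jay_v = z, Jay_a = z, Jwz_v = z)\n")
        emit_function(fh, f".dyn_imu_{s}", ["q", "v", "a", "rx", "ry", "p"],
                      exprs, unpack_qva + unpack_a + unpack_par, pre)

    fh.write(".dyn_imu_fns <- list(" +
             ", ".join([f"{s} = .dyn_imu_{s}" for s in imu]) + ")\n\n")

    # value-only variants (cheap line-search evaluations)
    exprs = [(f"out$res[, {i+1}L]", res[i]) for i in range(9)]
    assigns = unpack_qva + unpack_a
    assigns += "".join([f"  tau{j+1} <- tau[{j+1}L, ]\n" for j in range(6)])
    assigns += "".join([f"  {str(F[j])} <- f[{j+1}L, ]\n" for j in range(8)])
    assigns += unpack_par
    pre = "  n <- ncol(q)\n  out <- list(res = matrix(0, n, 9L))\n"
    emit_function(fh, ".dyn_eom_val", ["q", "v", "a", "tau", "f", "p"],
                  exprs, assigns, pre)

    exprs = []
    for k in range(4):
        exprs.append((f"out$px[, {k+1}L]", cp_px[k]))
        exprs.append((f"out$py[, {k+1}L]", cp_py[k]))
        exprs.append((f"out$vx[, {k+1}L]", cp_vx[k]))
        exprs.append((f"out$vy[, {k+1}L]", cp_vy[k]))
    pre = ("  n <- ncol(q)\n"
           "  out <- list(px = matrix(0, n, 4L), py = matrix(0, n, 4L),\n"
           "              vx = matrix(0, n, 4L), vy = matrix(0, n, 4L))\n")
    emit_function(fh, ".dyn_cpkin_val", ["q", "v", "p"], exprs,
                  unpack_qva + unpack_par, pre)

    for s, ent in imu.items():
        exprs = [("out$ax", ent["ax"]), ("out$ay", ent["ay"]), ("out$wz", ent["wz"])]
        pre = ("  n <- ncol(q)\n"
               "  out <- list(ax = numeric(n), ay = numeric(n), wz = numeric(n))\n")
        emit_function(fh, f".dyn_imu_{s}_val", ["q", "v", "a", "rx", "ry", "p"],
                      exprs, unpack_qva + unpack_a + unpack_par, pre)
    fh.write(".dyn_imu_val_fns <- list(" +
             ", ".join([f"{s} = .dyn_imu_{s}_val" for s in imu]) + ")\n\n")

    # weighted EOM Hessian
    exprs = []
    for i in range(9):
        for j in range(9):
            exprs.append((f"out$Hqq[, {i+1}L, {j+1}L]", Hqq[i][j]))
            exprs.append((f"out$Hqv[, {i+1}L, {j+1}L]", Hqv[i][j]))
            exprs.append((f"out$Hvv[, {i+1}L, {j+1}L]", Hvv[i][j]))
            exprs.append((f"out$Hqa[, {i+1}L, {j+1}L]", Hqa[i][j]))
    for i in range(9):
        for j in range(8):
            exprs.append((f"out$Hqf[, {i+1}L, {j+1}L]", Hqf[i][j]))
    assigns = unpack_qva
    assigns += "".join([f"  a{i+1} <- a[{i+1}L, ]\n" for i in range(9)])
    assigns += "".join([f"  {str(F[j])} <- f[{j+1}L, ]\n" for j in range(8)])
    assigns += "".join([f"  yw{i+1} <- yw[{i+1}L, ]\n" for i in range(9)])
    assigns += unpack_par
    pre = ("  n <- ncol(q)\n"
           "  z9 <- array(0, c(n, 9L, 9L))\n"
           "  out <- list(Hqq = z9, Hqv = z9, Hvv = z9, Hqa = z9,\n"
           "              Hqf = array(0, c(n, 9L, 8L)))\n")
    emit_function(fh, ".dyn_eom_whess", ["q", "v", "a", "f", "yw", "p"],
                  exprs, assigns, pre)

    # weighted contact-kinematics Hessian
    exprs = []
    for i in range(9):
        for j in range(9):
            exprs.append((f"out$Hqq[, {i+1}L, {j+1}L]", Cqq[i][j]))
            exprs.append((f"out$Hqv[, {i+1}L, {j+1}L]", Cqv[i][j]))
    assigns = unpack_qva
    for k in range(4):
        assigns += (f"  wpx{k+1} <- wpx[{k+1}L, ]\n  wpy{k+1} <- wpy[{k+1}L, ]\n"
                    f"  wvx{k+1} <- wvx[{k+1}L, ]\n  wvy{k+1} <- wvy[{k+1}L, ]\n")
    assigns += unpack_par
    pre = ("  n <- ncol(q)\n"
           "  z9 <- array(0, c(n, 9L, 9L))\n"
           "  out <- list(Hqq = z9, Hqv = z9)\n")
    emit_function(fh, ".dyn_cpkin_whess",
                  ["q", "v", "wpx", "wpy", "wvx", "wvy", "p"],
                  exprs, assigns, pre)
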