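"""Convert a DICOM-RT Plan (RTPLAN) file to the arcgate JSON plan dialect.

Usage: python rtplan_to_json.py <rtplan.dcm> <out.json>

Treatment arcs are emitted with their control-point sequences; setup and
imaging beams, and beams without MLC data, are skipped.  Leaf positions are
emitted bank A (60 leaves) then bank B (60 leaves), in millimetres, as
stored in LeafJawPositions for the MLCX device.
"""
import json
import sys

import pydicom


def jaw_positions(cp, carried):
    x = carried.get("X")
    y = carried.get("Y")
    for bld in getattr(cp, "BeamLimitingDevicePositionSequence", []):
        t = bld.RTBeamLimitingDeviceType
        if t in ("X", "ASYMX"):
            x = [float(v) for v in bld.LeafJawPositions]
        elif t in ("Y", "ASYMY"):
            y = [float(v) for v in bld.LeafJawPositions]
    carried["X"], carried["Y"] = x, y
    if x is None or y is None:
        return None
    return [x[0], x[1], y[0], y[1]]


def mlc_positions(cp, carried):
    for bld in getattr(cp, "BeamLimitingDevicePositionSequence", []):
        if bld.RTBeamLimitingDeviceType in ("MLCX", "MLCY"):
            carried["MLC"] = [float(v) for v in bld.LeafJawPositions]
    return carried.get("MLC")


def convert(path):
    ds = pydicom.dcmread(path, force=True)
    plan_id = str(getattr(ds, "RTPlanLabel", "") or
                  getattr(ds, "SOPInstanceUID", "plan"))
    arcs = []
    for beam in getattr(ds, "BeamSequence", []):
        if str(getattr(beam, "TreatmentDeliveryType", "TREATMENT")) != "TREATMENT":
            continue
        cps = getattr(beam, "ControlPointSequence", [])
        if not cps:
            continue
        carried = {}
        gantry = None
        records = []
        has_mlc = False
        final_weight = float(getattr(beam, "FinalCumulativeMetersetWeight", 1.0))
        for i, cp in enumerate(cps):
            if hasattr(cp, "GantryAngle"):
                gantry = float(cp.GantryAngle)
            jaws = jaw_positions(cp, carried)
            mlc = mlc_positions(cp, carried)
            if mlc is not None:
                has_mlc = True
            w = float(cp.CumulativeMetersetWeight)
            if final_weight:
                w /= final_weight
            records.append({
                "index": int(getattr(cp, "ControlPointIndex", i)),
                "meterset_weight": w,
                "jaws": jaws,
                "gantry_angle": gantry if gantry is not None else 0.0,
                "leaf_positions": mlc,
            })
        if not has_mlc:
            sys.stderr.write(
                "beam '%s' has no MLC data; skipped\n"
                % str(getattr(beam, "BeamName", beam.BeamNumber)))
            continue
        # carry MLC/jaws forward for control points that omitted them
        last_mlc, last_jaws = None, None
        for r in records:
            if r["leaf_positions"] is None:
                r["leaf_positions"] = last_mlc
            if r["jaws"] is None:
                r["jaws"] = last_jaws
            last_mlc, last_jaws = r["leaf_positions"], r["jaws"]
        if any(r["leaf_positions"] is None or r["jaws"] is None for r in records):
            raise SystemExit(
                "beam '%s': control points precede first MLC/jaw state"
                % str(getattr(beam, "BeamName", beam.BeamNumber)))
        arcs.append({
            "arc_id": str(getattr(beam, "BeamName", "") or beam.BeamNumber),
            "gpr": None,
            "control_points": records,
        })
    return {"plan_id": plan_id, "arcs": arcs}


def main():
    if len(sys.argv) != 3:
        raise SystemExit(__doc__)
    doc = convert(sys.argv[1])
    with open(sys.argv[2], "w") as fh:
        json.dump(doc, fh)


if __name__ == "__main__":
    main()
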