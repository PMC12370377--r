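"""Write a minimal DICOM-RT Plan from an arcgate JSON plan file.

Usage: python json_to_rtplan.py <plan.json> <out.dcm>

Emits just enough of the RTPLAN information model (BeamSequence with
ControlPointSequence, MLCX + ASYMX/ASYMY BeamLimitingDevicePositionSequence)
for round-trip tests of the package's DICOM reader.  Not a clinical export.
"""
import json
import sys

import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid

RTPLAN_SOP_CLASS = "1.2.840.10008.5.1.4.1.1.481.5"


def build(doc):
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = RTPLAN_SOP_CLASS
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian

    ds = Dataset()
    ds.file_meta = meta
    ds.SOPClassUID = RTPLAN_SOP_CLASS
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.Modality = "RTPLAN"
    ds.RTPlanLabel = str(doc.get("plan_id", "plan"))
    ds.BeamSequence = []
    for bi, arc in enumerate(doc["arcs"], start=1):
        beam = Dataset()
        beam.BeamNumber = bi
        beam.BeamName = str(arc.get("arc_id", bi))
        beam.TreatmentDeliveryType = "TREATMENT"
        beam.BeamType = "DYNAMIC"
        beam.FinalCumulativeMetersetWeight = 1.0
        beam.ControlPointSequence = []
        for cp in arc["control_points"]:
            c = Dataset()
            c.ControlPointIndex = int(cp["index"])
            c.CumulativeMetersetWeight = float(cp["meterset_weight"])
            c.GantryAngle = float(cp["gantry_angle"])
            jaws = [float(v) for v in cp["jaws"]]
            bx = Dataset()
            bx.RTBeamLimitingDeviceType = "ASYMX"
            bx.LeafJawPositions = jaws[0:2]
            by = Dataset()
            by.RTBeamLimitingDeviceType = "ASYMY"
            by.LeafJawPositions = jaws[2:4]
            mlc = Dataset()
            mlc.RTBeamLimitingDeviceType = "MLCX"
            mlc.LeafJawPositions = [float(v) for v in cp["leaf_positions"]]
            c.BeamLimitingDevicePositionSequence = [bx, by, mlc]
            beam.ControlPointSequence.append(c)
        ds.BeamSequence.append(beam)
    return ds


def main():
    if len(sys.argv) != 3:
        raise SystemExit(__doc__)
    with open(sys.argv[1]) as fh:
        doc = json.load(fh)
    ds = build(doc)
    pydicom.dcmwrite(sys.argv[2], ds, enforce_file_format=True)


if __name__ == "__main__":
    main()
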