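HeadTop
HeadFront
HeadLeft
HeadRight
C7
Neck
T8
T12
L5
Sternum
Xiphoid
RightClavicle
LeftClavicle
RightScapula
LeftScapula
RightShoulder
LeftShoulder
RightAcromion
LeftAcromion
RightUpperArm
LeftUpperArm
RightUpperArmFront
LeftUpperArmFront
RightElbowLat
LeftElbowLat
RightElbowMed
LeftElbowMed
RightForearm
LeftForearm
RightWristRad
LeftWristRad
RightWristUln
LeftWristUln
RightHand
LeftHand
RightHandTip
LeftHandTip
RightASIS
LeftASIS
RightPSIS
LeftPSIS
Sacrum
RightThigh
LeftThigh
RightThighFront
LeftThighFront
RightKneeLat
LeftKneeLat
RightKneeMed
LeftKneeMed
RightShank
LeftShank
RightAnkle
LeftAnkle
RightAnkleMed
LeftAnkleMed
RightHeel
LeftHeel
RightToe
LeftToe
RightFootLat
LeftFootLat
RightToeTip
LeftToeTip
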