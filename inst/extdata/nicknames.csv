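name,variant
robert,bob
robert,rob
william,bill
william,will
elizabeth,liz
elizabeth,beth
margaret,peggy
katherine,kate
michael,mike
james,jim
john,jack
richard,rick
thomas,tom
charles,chuck
patricia,patty
jennifer,jen
susan,sue
deborah,debbie
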